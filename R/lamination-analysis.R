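#' Fit a power law to a deformation series
#'
#' Ordinary least squares on `(ln x, ln y)`: `f(x) = a * x^b` with
#' `a = exp(intercept)`, `b = slope`; the coefficient of determination is that
#' of the log-space regression, matching the spreadsheet-style "curve of best
#' fit" used for deformation versus cylinder count.
#'
#' @param series a `deformation_series` from [run_lamination_series()], or any
#'   data.frame whose first two columns are x and y, or a numeric vector of y
#'   values (x taken as `seq_along(y)`).
#' @return an object of class `power_law_fit` with fields `a`, `b`,
#'   `r_squared`, `n_points` and `morphotype`.
#' @export
fit_power_law <- function(series) {
  if (is.numeric(series) && is.null(dim(series))) {
    x <- seq_along(series); y <- as.numeric(series); lab <- ""
  } else {
    x <- as.numeric(series[[1]]); y <- as.numeric(series[[2]])
    lab <- attr(series, "morphotype") %||% ""
  }
  if (length(y) < 3L) stop("need at least 3 points for a power-law fit")
  if (any(y <= 0) || any(x <= 0)) {
    stop("power-law fit requires strictly positive x and y values")
  }
  fit <- stats::lm(log(y) ~ log(x))
  # summary() warns on an exactly power-law input; a perfect fit is valid here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(a = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 n_points = length(y),
                 morphotype = lab),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit>%s f(x) = %.4f * x^%.3f  (R^2 = %.4f, n = %d)\n",
              if (nzchar(x$morphotype)) paste0(" [", x$morphotype, "]") else "",
              x$a, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' Extrapolate deformation to a given cylinder count
#'
#' Evaluates the fitted power law `a * n^b` at the cylinder count that meets
#' the observed procuticle thickness.
#'
#' @param fit a `power_law_fit`.
#' @param n_cylinders cylinder count (>= 1).
#' @param digits decimal places for reporting in nm (default 4, matching the
#'   published table; use `NA` for no rounding).
#' @return extrapolated deformation in the units of the fitted series.
#' @export
extrapolate_deformation <- function(fit, n_cylinders, digits = 4) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (any(n_cylinders < 1)) stop("n_cylinders must be >= 1")
  v <- fit$a * n_cylinders^fit$b
  if (is.na(digits)) v else round(v, digits)
}

#' Percent change between two values
#'
#' `100 * (after - before) / before`, rounded to the nearest integer percent
#' for reporting (`digits = 0`).
#'
#' @param before,after scalars; `before` must be non-zero.
#' @param digits rounding for the reported percentage (default 0; `NA` for no
#'   rounding).
#' @return percent change.
#' @export
percent_change <- function(before, after, digits = 0) {
  if (any(before == 0)) stop("'before' must be non-zero")
  v <- 100 * (after - before) / before
  if (is.na(digits)) v else round(v, digits)
}

#' Percent reduction relative to a reference
#'
#' `100 * (1 - value / reference)`.
#'
#' @param reference positive reference value.
#' @param value compared value.
#' @param digits rounding (default 0; `NA` for no rounding).
#' @return percent reduction.
#' @export
percent_reduction <- function(reference, value, digits = 0) {
  if (any(reference <= 0)) stop("'reference' must be > 0")
  v <- 100 * (1 - value / reference)
  if (is.na(digits)) v else round(v, digits)
}

#' Fit and extrapolate all reference laminate series
#'
#' Convenience wrapper: fits the power law to each laminate model column of a
#' deformation table and extrapolates to the cylinder counts that meet the
#' observed procuticle thicknesses.
#'
#' @param deformation a `data.frame` like [laminate_deformation_reference()]:
#'   first column cylinder counts, remaining columns one deformation series
#'   (nm) per laminate model.
#' @param cylinders named integer vector of extrapolation cylinder counts, one
#'   per series column (default: the published 13 / 16 / 9 mapping).
#' @return a `data.frame` with one row per model: `a`, `b`, `r_squared`,
#'   `n_extrapolation`, `deformation_nm`.
#' @export
extrapolation_table <- function(deformation = laminate_deformation_reference(),
                                cylinders = c(model_i_nm = 13L,
                                              model_ii_nm = 16L,
                                              model_iii_nm = 9L)) {
  cols <- names(deformation)[-1]
  if (!all(cols %in% names(cylinders))) {
    stop("cylinders must name every series column: ",
         paste(cols, collapse = ", "))
  }
  rows <- lapply(cols, function(cn) {
    f <- fit_power_law(deformation[, c(1, match(cn, names(deformation)))])
    data.frame(model = sub("_nm$", "", cn), a = f$a, b = f$b,
               r_squared = f$r_squared,
               n_extrapolation = as.integer(cylinders[[cn]]),
               deformation_nm = extrapolate_deformation(f, cylinders[[cn]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
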