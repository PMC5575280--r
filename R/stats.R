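#' Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. The reported statistic is
#' `U = min(U1, U2)`. The p-value is exact (distribution of U under random
#' rank assignment) when both samples are at or below `exact_max` and no ties
#' are present, otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max largest per-group size for the exact null distribution
#'   (default 20).
#' @return list with `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && max(n1, n2) <= exact_max) {
    # exact two-sided p from the symmetric null distribution of U
    p <- min(1, 2 * stats::pwilcox(U, n1, n2))
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(c(x, y))
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_corr)
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu + 0.5) / sqrt(sigma2)   # continuity-corrected, U <= mu
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "normal-approximation"
  }
  list(U = U, p_value = p, method = method)
}

#' Two-sample pooled-variance t test
#'
#' Student's t with pooled variance (the classical equal-variance form).
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return list with `t`, `p_value`, `df`.
#' @export
students_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero pooled variance: t statistic undefined")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Two-level nested ANOVA
#'
#' Individuals nested in treatment, repeated measurements per individual.
#' Sums of squares partition exactly
#' (`SS_total = SS_treatment + SS_individual + SS_residual`); the treatment
#' effect is tested against the among-individual mean square with
#' `df = (number of individuals - number of treatments)`, which controls for
#' inter-individual differences in hierarchical measurement designs. For
#' unbalanced data the same partition holds but the treatment F test is the
#' unweighted-means approximation; the output is flagged.
#'
#' @param data `data.frame` with columns `value`, `treatment`,
#'   `individual_id` (at least 2 individuals per treatment, at least 2
#'   measurements per individual).
#' @return list of class `nested_anova`: the ANOVA `table` (`data.frame` with
#'   rows treatment / individual / residual), `F_treatment`, `p_treatment`,
#'   `balanced`, `flag`.
#' @export
nested_anova <- function(data) {
  need <- c("value", "treatment", "individual_id")
  if (!all(need %in% names(data))) {
    stop("data needs columns: ", paste(need, collapse = ", "))
  }
  data$treatment <- as.character(data$treatment)
  data$individual_id <- as.character(data$individual_id)
  tr_of_ind <- tapply(data$treatment, data$individual_id,
                      function(v) unique(v))
  if (any(lengths(tr_of_ind) != 1L)) {
    stop("each individual must belong to exactly one treatment")
  }
  ind_per_tr <- table(unlist(tr_of_ind))
  if (any(ind_per_tr < 2L)) stop("need >= 2 individuals per treatment")
  meas_per_ind <- table(data$individual_id)
  if (any(meas_per_ind < 2L)) stop("need >= 2 measurements per individual")

  y <- data$value
  gm <- mean(y)
  ind_mean <- tapply(y, data$individual_id, mean)
  ind_n <- tapply(y, data$individual_id, length)
  tr_mean <- tapply(y, data$treatment, mean)
  tr_n <- tapply(y, data$treatment, length)

  ss_total <- sum((y - gm)^2)
  ss_treatment <- sum(tr_n * (tr_mean - gm)^2)
  ss_individual <- sum(ind_n * (ind_mean[names(ind_n)] -
                                  tr_mean[unlist(tr_of_ind)[names(ind_n)]])^2)
  ss_residual <- sum((y - ind_mean[data$individual_id])^2)

  a <- length(tr_mean)
  b <- length(ind_mean)
  N <- length(y)
  df_tr <- a - 1L
  df_ind <- b - a
  df_res <- N - b

  balanced <- length(unique(meas_per_ind)) == 1L &&
    length(unique(ind_per_tr)) == 1L
  all_equal <- ss_total <= .Machine$double.eps * max(1, sum(y^2))

  ms_tr <- ss_treatment / df_tr
  ms_ind <- ss_individual / df_ind
  ms_res <- ss_residual / df_res
  if (all_equal || ms_ind == 0) {
    Ftr <- NA_real_; ptr <- NA_real_
    flag <- "degenerate: no variance, F undefined"
  } else {
    Ftr <- ms_tr / ms_ind
    ptr <- stats::pf(Ftr, df_tr, df_ind, lower.tail = FALSE)
    flag <- if (balanced) NA_character_ else
      "unbalanced design: treatment F is the unweighted-means approximation"
  }
  tab <- data.frame(
    term = c("treatment", "individual(treatment)", "residual"),
    df = c(df_tr, df_ind, df_res),
    sum_sq = c(ss_treatment, ss_individual, ss_residual),
    mean_sq = c(ms_tr, ms_ind, ms_res),
    F = c(Ftr, ss_individual / df_ind / ms_res, NA),
    p = c(ptr, stats::pf(ms_ind / ms_res, df_ind, df_res,
                         lower.tail = FALSE), NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab, F_treatment = Ftr, p_treatment = ptr,
                 balanced = balanced, flag = flag,
                 ss_total = ss_total),
            class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat("Two-level nested ANOVA (treatment tested against individuals)\n")
  print(x$table, row.names = FALSE)
  if (!is.na(x$flag)) cat("note:", x$flag, "\n")
  invisible(x)
}

#' Significance stars
#'
#' Renders the significance convention used throughout the reporting tables:
#' `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.005.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star codes (`"ns"` when p > 0.05).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi <= 0.005) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else "ns"
  }, character(1))
}
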