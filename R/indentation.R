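#' Indenter geometry specification
#'
#' Tip geometry and sample Poisson's ratio for Hertz-model analysis. The AFM
#' probe is a four-sided pyramid (face angle `alpha`), the microindenter tip a
#' parabolic body of given radius.
#'
#' @param kind `"pyramidal"` or `"parabolic"`.
#' @param face_angle_deg pyramid face angle in degrees, in (0, 90)
#'   (pyramidal tips; default 35).
#' @param tip_radius_m tip radius in metres (> 0, parabolic tips).
#' @param poisson_ratio sample Poisson's ratio in `[0, 0.5)`; defaults: 0.5 is
#'   conventional for soft hydrated cuticle under AFM, 0.15 matches the shell
#'   models for the microindenter.
#' @return an object of class `indenter_spec`.
#' @export
indenter_spec <- function(kind = c("pyramidal", "parabolic"),
                          face_angle_deg = 35,
                          tip_radius_m = NULL,
                          poisson_ratio = NULL) {
  kind <- match.arg(kind)
  if (is.null(poisson_ratio)) {
    poisson_ratio <- if (kind == "pyramidal") 0.5 else 0.15
  }
  # 0.5 (incompressible) is admissible for Hertz inversion, unlike in the FEM
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    stop("poisson_ratio must lie in [0, 0.5]")
  }
  if (kind == "pyramidal") {
    if (face_angle_deg <= 0 || face_angle_deg >= 90) {
      stop("face_angle_deg must lie in (0, 90)")
    }
  } else {
    if (is.null(tip_radius_m) || tip_radius_m <= 0) {
      stop("parabolic tips need tip_radius_m > 0")
    }
  }
  structure(list(kind = kind, face_angle_deg = face_angle_deg,
                 tip_radius_m = tip_radius_m, poisson_ratio = poisson_ratio),
            class = "indenter_spec")
}

# geometry prefactor g such that F = g * E * delta^p
hertz_prefactor <- function(spec) {
  if (spec$kind == "pyramidal") {
    list(g = tan(spec$face_angle_deg * pi / 180) /
           (sqrt(2) * (1 - spec$poisson_ratio^2)), p = 2)
  } else {
    list(g = 4 / 3 * sqrt(spec$tip_radius_m) /
           (1 - spec$poisson_ratio^2), p = 1.5)
  }
}

#' Hertz force for a four-sided pyramidal tip
#'
#' `F = tan(alpha) / sqrt(2) * E / (1 - nu^2) * delta^2`.
#'
#' @param young_modulus_pa sample Young's modulus in Pa.
#' @param depth_m indentation depth in metres (>= 0; vectorised).
#' @param spec a pyramidal [indenter_spec()].
#' @return force in newtons.
#' @export
hertz_force_pyramidal <- function(young_modulus_pa, depth_m, spec) {
  stopifnot(inherits(spec, "indenter_spec"), spec$kind == "pyramidal")
  if (any(depth_m < 0)) stop("depth_m must be >= 0")
  h <- hertz_prefactor(spec)
  h$g * young_modulus_pa * depth_m^h$p
}

#' Hertz force for a parabolic tip
#'
#' `F = 4/3 * sqrt(r) * E / (1 - nu^2) * delta^(3/2)`.
#'
#' @inheritParams hertz_force_pyramidal
#' @param spec a parabolic [indenter_spec()].
#' @return force in newtons.
#' @export
hertz_force_parabolic <- function(young_modulus_pa, depth_m, spec) {
  stopifnot(inherits(spec, "indenter_spec"), spec$kind == "parabolic")
  if (any(depth_m < 0)) stop("depth_m must be >= 0")
  h <- hertz_prefactor(spec)
  h$g * young_modulus_pa * depth_m^h$p
}

#' Force-distance curve
#'
#' @param distance_m monotone approach distance in metres.
#' @param force_n measured force in newtons (same length, >= 10 samples).
#' @param instrument `"afm"` or `"microindenter"`.
#' @param spring_constant_n_per_m cantilever spring constant (N/m) for the
#'   sample-deformation correction; `NA` to skip.
#' @param tip character descriptor of the probe.
#' @return an object of class `force_curve`.
#' @export
force_curve <- function(distance_m, force_n,
                        instrument = c("afm", "microindenter"),
                        spring_constant_n_per_m = NA_real_, tip = "") {
  instrument <- match.arg(instrument)
  if (length(distance_m) != length(force_n)) {
    stop("distance and force must have equal length")
  }
  if (length(distance_m) < 10L) stop("force curve needs at least 10 samples")
  d <- diff(distance_m)
  if (!(all(d > 0) || all(d < 0))) stop("distance must be strictly monotone")
  structure(list(distance_m = as.numeric(distance_m),
                 force_n = as.numeric(force_n),
                 instrument = instrument,
                 spring_constant_n_per_m = spring_constant_n_per_m,
                 tip = tip),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %s, %d samples, force range [%.3g, %.3g] N\n",
              x$instrument, length(x$force_n), min(x$force_n), max(x$force_n)))
  invisible(x)
}

#' Detect the tip-sample contact point
#'
#' Estimates the pre-contact baseline from the leading fraction of the curve
#' and returns the last sample at or below `baseline mean + k * baseline SD`
#' before the first crossing that stays above the threshold for at least
#' `sustain` samples.
#'
#' @param curve a [force_curve()].
#' @param k threshold in baseline standard deviations (default 5).
#' @param baseline_fraction leading fraction of samples used to estimate the
#'   baseline (default 0.15, at least 5 samples).
#' @param sustain number of consecutive above-threshold samples required
#'   (default 5).
#' @param refine logical; after the threshold crossing, refine the contact
#'   location by a one-dimensional least-squares fit of the contact offset in
#'   the Hertz model (default `TRUE`). The pure crossing rule systematically
#'   lags the true contact on a smooth loading onset.
#' @return integer sample index of the contact point.
#' @export
detect_contact_point <- function(curve, k = 5, baseline_fraction = 0.15,
                                 sustain = 5L, refine = TRUE) {
  stopifnot(inherits(curve, "force_curve"))
  f <- curve$force_n
  n <- length(f)
  nb <- max(5L, floor(baseline_fraction * n))
  base <- f[seq_len(nb)]
  thr <- mean(base) + k * stats::sd(base)
  above <- f > thr
  run <- 0L
  cross <- NA_integer_
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= sustain) { cross <- i - sustain + 1L; break }
  }
  if (is.na(cross)) stop("no contact detected")
  ci <- max(1L, cross - 1L)
  if (!refine || cross <= 2L) return(ci)

  # refine: fit F = g E (d - d0)^p over the contact offset d0; the modulus
  # enters linearly, so each candidate d0 costs one closed-form projection
  p <- if (curve$instrument == "afm") 2 else 1.5
  d <- curve$distance_m
  if (d[1] > d[n]) d <- -d   # approach direction: make distance increasing
  upr_i <- min(n - 10L, cross + sustain)
  sse <- function(c0) {
    # baseline offset re-estimated per candidate from its pre-contact part
    off <- mean(f[seq_len(c0)])
    idx <- (c0 + 1L):n
    x <- (d[idx] - d[c0])^p
    y <- f[idx] - off
    E <- sum(y * x) / sum(x * x)
    sum((y - E * x)^2) + sum((f[seq_len(c0)] - off)^2)
  }
  cand <- seq_len(max(1L, upr_i))
  max(1L, cand[which.min(vapply(cand, sse, numeric(1)))])
}

#' Fit the Young's modulus from a force-distance curve
#'
#' Detects the contact point, converts distance beyond contact into
#' indentation depth (subtracting the cantilever deflection `F / k` when a
#' spring constant is available), and estimates E by linear least squares of
#' force against the tip geometry's depth power. For AFM curves the fit
#' window is capped at the instrument limits (10 nN maximal force, 50 nm
#' maximal depth).
#'
#' @param curve a [force_curve()].
#' @param spec an [indenter_spec()] matching the instrument.
#' @param contact_index optional known contact sample; detected when `NULL`.
#' @return an object of class `hertz_fit` with fields `young_modulus_pa`,
#'   `contact_index`, `residual_rms_n`, `depth_range_m` and `n_fit`.
#' @export
fit_young_modulus <- function(curve, spec, contact_index = NULL) {
  stopifnot(inherits(curve, "force_curve"), inherits(spec, "indenter_spec"))
  ci <- contact_index %||% detect_contact_point(curve)
  n <- length(curve$force_n)
  if (n - ci < 10L) stop("need at least 10 post-contact samples")
  idx <- (ci + 1L):n
  # approach direction: depth grows away from the contact sample
  delta <- abs(curve$distance_m[idx] - curve$distance_m[ci])
  f <- curve$force_n[idx] - curve$force_n[ci]
  kspr <- curve$spring_constant_n_per_m
  if (is.finite(kspr) && kspr > 0) delta <- delta - f / kspr
  keep <- delta > 0 & f > 0
  if (curve$instrument == "afm") {
    keep <- keep & delta <= 50e-9 & f <= 10e-9
  }
  if (sum(keep) < 5L) stop("too few usable samples in the fit window")
  delta <- delta[keep]; f <- f[keep]
  h <- hertz_prefactor(spec)
  x <- h$g * delta^h$p
  E <- sum(f * x) / sum(x * x)
  if (!is.finite(E) || E <= 0) {
    stop("fitted Young's modulus is not positive; curve flagged as invalid")
  }
  res <- f - E * x
  structure(list(young_modulus_pa = E,
                 contact_index = ci,
                 residual_rms_n = sqrt(mean(res^2)),
                 depth_range_m = range(delta),
                 n_fit = length(f)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.4g Pa (contact at sample %d, %d samples, RMS residual %.3g N)\n",
              x$young_modulus_pa, x$contact_index, x$n_fit, x$residual_rms_n))
  invisible(x)
}

#' Detect the critical (collapse) force
#'
#' Scans a microindenter curve for the first sample-to-sample force drop
#' exceeding `drop_threshold` of the running force maximum; the reported
#' critical force is the force at the local maximum immediately preceding the
#' drop, i.e. the maximum force the carapace bears before structural
#' collapse.
#'
#' @param curve a [force_curve()] (microindenter).
#' @param drop_threshold fraction of the running maximum that a single-step
#'   decrease must exceed to qualify as a collapse (default 0.15).
#' @return an object of class `critical_force_result` with fields
#'   `critical_force_n`, `drop_index` and `drop_fraction`.
#' @export
detect_critical_force <- function(curve, drop_threshold = 0.15) {
  stopifnot(inherits(curve, "force_curve"))
  f <- curve$force_n
  n <- length(f)
  runmax <- cummax(f)
  for (i in 2:n) {
    drop <- f[i - 1] - f[i]
    if (runmax[i - 1] > 0 && drop > drop_threshold * runmax[i - 1]) {
      j <- i - 1L
      while (j > 1L && f[j - 1L] > f[j]) j <- j - 1L
      return(structure(list(critical_force_n = f[j],
                            drop_index = j,
                            drop_fraction = drop / runmax[i - 1]),
                       class = "critical_force_result"))
    }
  }
  stop("no collapse detected")
}

#' @export
print.critical_force_result <- function(x, ...) {
  cat(sprintf("<critical_force_result> %.4g N at sample %d (drop fraction %.2f)\n",
              x$critical_force_n, x$drop_index, x$drop_fraction))
  invisible(x)
}

#' Read / write force curves as CSV
#'
#' Two-column CSV (`distance_m`, `force_n`) preceded by a commented metadata
#' header block (`# key: value` lines for instrument, spring constant and tip
#' descriptor).
#'
#' @param path file path.
#' @param curve a [force_curve()] (writer only).
#' @return the reader returns a [force_curve()]; the writer returns `path`
#'   invisibly.
#' @export
read_force_curve_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  d <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                         value = TRUE), collapse = "\n"))
  force_curve(d$distance_m, d$force_n,
              instrument = meta[["instrument"]] %||% "afm",
              spring_constant_n_per_m =
                as.numeric(meta[["spring_constant_n_per_m"]] %||% NA),
              tip = meta[["tip"]] %||% "")
}

#' @rdname read_force_curve_csv
#' @export
write_force_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  hdr <- c(sprintf("# instrument: %s", curve$instrument),
           sprintf("# spring_constant_n_per_m: %s",
                   format(curve$spring_constant_n_per_m)),
           sprintf("# tip: %s", curve$tip))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(distance_m = curve$distance_m,
                              force_n = curve$force_n),
                   con, row.names = FALSE)
  invisible(path)
}
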