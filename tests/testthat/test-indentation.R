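afm_spec <- function(...) indenter_spec("pyramidal", ...)
micro_spec <- function(r = 12.37e-6, ...) {
  indenter_spec("parabolic", tip_radius_m = r, ...)
}

test_that("pyramidal Hertz force follows the quadratic depth law", {
  sp <- afm_spec(face_angle_deg = 35, poisson_ratio = 0.5)
  expect_equal(hertz_force_pyramidal(2.93e6, 0, sp), 0)
  f1 <- hertz_force_pyramidal(2.93e6, 50e-9, sp)
  expect_equal(hertz_force_pyramidal(2.93e6, 100e-9, sp), 4 * f1)
  # independent hand evaluation of tan(a)/sqrt(2) * E/(1-v^2) * d^2
  expect_equal(f1, tan(35 * pi / 180) / sqrt(2) * 2.93e6 / (1 - 0.25) *
                 (50e-9)^2, tolerance = 1e-12)
  expect_error(hertz_force_pyramidal(1e6, -1e-9, sp), ">= 0")
})

test_that("parabolic Hertz force follows the 3/2-power depth law", {
  sp <- micro_spec(poisson_ratio = 0.15)
  expect_equal(hertz_force_parabolic(195.39e3, 0, sp), 0)
  f1 <- hertz_force_parabolic(195.39e3, 1.25e-6, sp)
  expect_equal(hertz_force_parabolic(195.39e3, 5e-6, sp), 8 * f1)
  expect_equal(hertz_force_parabolic(195.39e3, 5e-6, sp),
               4 / 3 * sqrt(12.37e-6) * 195.39e3 / (1 - 0.15^2) * (5e-6)^1.5,
               tolerance = 1e-12)
  # with vanishing Poisson ratio the (1 - v^2) factor drops out
  sp0 <- micro_spec(poisson_ratio = 0)
  expect_equal(hertz_force_parabolic(1e5, 1e-6, sp0),
               4 / 3 * sqrt(12.37e-6) * 1e5 * (1e-6)^1.5, tolerance = 1e-12)
})

test_that("contact detection finds the inserted contact within 3 samples", {
  sp <- afm_spec()
  hits <- vapply(1:20, function(s) {
    cv <- gen_force_curve(2.93e6, sp, "afm", baseline_sd_frac = 0.01,
                          seed = 100 + s)
    detect_contact_point(cv) - attr(cv, "truth")$contact_index
  }, numeric(1))
  expect_true(all(abs(hits) <= 3))

  # all-zero force: nothing to detect
  flat <- force_curve(seq(0, 1e-6, length.out = 50), rep(0, 50), "afm")
  expect_error(detect_contact_point(flat), "no contact detected")

  # noiseless curve starting right at contact
  d <- seq(0, 50e-9, length.out = 60)
  cv0 <- force_curve(d, hertz_force_pyramidal(1e6, d, sp), "afm")
  expect_identical(detect_contact_point(cv0), 1L)
})

test_that("noiseless curves round-trip the modulus to 1e-6 relative", {
  for (case in list(list(sp = afm_spec(), E = 1.66e6, inst = "afm"),
                    list(sp = afm_spec(), E = 15.59e6, inst = "afm"),
                    list(sp = micro_spec(), E = 103.96e3,
                         inst = "microindenter"),
                    list(sp = micro_spec(), E = 262.84e3,
                         inst = "microindenter"))) {
    cv <- gen_force_curve(case$E, case$sp, case$inst)
    fit <- fit_young_modulus(cv, case$sp)
    expect_equal(fit$young_modulus_pa, case$E, tolerance = 1e-6)
  }
})

test_that("fitted modulus scales with force and ignores distance offsets", {
  sp <- afm_spec()
  cv <- gen_force_curve(2e6, sp, "afm", baseline_sd_frac = 0.005,
                        multiplicative_sd = 0.02, seed = 5)
  E1 <- fit_young_modulus(cv, sp)$young_modulus_pa
  cv2 <- force_curve(cv$distance_m, cv$force_n * 3, "afm")
  # 3x force exceeds the 10 nN AFM window cap; supply the known contact
  E2 <- fit_young_modulus(cv2, sp,
                          contact_index = detect_contact_point(cv))$young_modulus_pa
  expect_equal(E2 / E1, 3, tolerance = 0.02)
  cv3 <- force_curve(cv$distance_m + 1.7e-8, cv$force_n, "afm")
  E3 <- fit_young_modulus(cv3, sp)$young_modulus_pa
  expect_equal(E3, E1, tolerance = 1e-4)
})

test_that("median modulus of noisy replicate curves stays within 5%", {
  sp <- afm_spec()
  E_true <- 15.59e6
  est <- vapply(1:200, function(s) {
    cv <- gen_force_curve(E_true, sp, "afm", baseline_sd_frac = 0.01,
                          multiplicative_sd = 0.05, seed = 2000 + s)
    fit_young_modulus(cv, sp)$young_modulus_pa
  }, numeric(1))
  expect_equal(median(est), E_true, tolerance = 0.05)
})

test_that("spring-constant metadata triggers the deflection correction", {
  sp <- afm_spec()
  k <- 0.1
  # synthesize a curve in piezo-travel coordinates: measured z displacement is
  # indentation depth plus cantilever deflection F / k; the contact sample
  # (depth 0, force 0) closes the pre-contact baseline
  pre <- seq(-20e-9, 0, length.out = 40)
  delta <- seq(0, 45e-9, length.out = 90)[-1]
  Fv <- hertz_force_pyramidal(3e6, delta, sp)
  dz <- c(pre, delta + Fv / k)
  cv <- force_curve(dz, c(numeric(40), Fv), "afm",
                    spring_constant_n_per_m = k)
  fit <- fit_young_modulus(cv, sp, contact_index = 40L)
  expect_equal(fit$young_modulus_pa, 3e6, tolerance = 1e-6)
  # ignoring the correction underestimates the modulus
  cv_nok <- force_curve(dz, c(numeric(40), Fv), "afm")
  fit2 <- fit_young_modulus(cv_nok, sp, contact_index = 40L)
  expect_lt(fit2$young_modulus_pa, 0.99 * fit$young_modulus_pa)
})

test_that("critical-force detection reports the pre-collapse maximum", {
  sp <- micro_spec()
  # monotone rising curve: no collapse
  d <- seq(0, 5e-6, length.out = 80)
  rising <- force_curve(d, hertz_force_parabolic(2e5, d, sp), "microindenter")
  expect_error(detect_critical_force(rising), "no collapse detected")

  # synthetic curve rising to 1.84 mN, then a 40% drop: choose the depth
  # range so the curve peaks at twice the collapse force
  g <- 4 / 3 * sqrt(12.37e-6) * 2e5 / (1 - 0.15^2)
  dmax <- (2 * 1.84e-3 / g)^(2 / 3)
  cv <- gen_force_curve(2e5, sp, "microindenter", max_depth_m = dmax,
                        collapse = list(at_force_n = 1.84e-3,
                                        drop_fraction = 0.4))
  res <- detect_critical_force(cv)
  expect_equal(res$critical_force_n, attr(cv, "truth")$collapse_force_n,
               tolerance = 1e-10)
  expect_equal(res$critical_force_n, 1.84e-3, tolerance = 0.02)
  expect_gte(res$drop_fraction, 0.15)
  expect_equal(res$critical_force_n, cv$force_n[res$drop_index])

  # two drops: the first qualifying one wins
  f2 <- c(seq(0, 1, length.out = 20), 0.6, seq(0.62, 1.4, length.out = 20),
          0.7, seq(0.72, 1, length.out = 8))
  cv2 <- force_curve(seq_along(f2) * 1e-7, f2 * 1e-3, "microindenter")
  r2 <- detect_critical_force(cv2)
  expect_equal(r2$critical_force_n, 1e-3)
  expect_identical(r2$drop_index, 20L)
})

test_that("force curves round-trip through the CSV format", {
  cv <- gen_force_curve(2.5e6, afm_spec(), "afm", baseline_sd_frac = 0.01,
                        seed = 9, spring_constant_n_per_m = 0.1)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_force_curve_csv(cv, tmp)
  back <- read_force_curve_csv(tmp)
  expect_equal(back$distance_m, cv$distance_m)
  expect_equal(back$force_n, cv$force_n)
  expect_identical(back$instrument, "afm")
  expect_equal(back$spring_constant_n_per_m, 0.1)
})

test_that("indenter specifications validate their geometry", {
  expect_error(indenter_spec("pyramidal", face_angle_deg = 95), "face_angle")
  expect_error(indenter_spec("parabolic"), "tip_radius")
  expect_error(indenter_spec("pyramidal", poisson_ratio = 0.7), "poisson")
  expect_error(force_curve(c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9), 1:10),
               "monotone")
})
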