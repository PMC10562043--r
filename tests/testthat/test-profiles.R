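test_that("erf matches its integral definition and is odd, bounded, monotone", {
  # independent oracle: adaptive quadrature of the defining integral
  erf_quad <- function(z)
    2 / sqrt(pi) * integrate(function(t) exp(-t^2), 0, z,
                             rel.tol = 1e-12)$value
  for (z in c(0.1, 0.5, 1, 2, 3))
    expect_equal(erf(z), erf_quad(z), tolerance = 1e-10)
  expect_identical(erf(0), 0)
  expect_equal(erf(1), 0.842700792949715, tolerance = 1e-12)
  zs <- seq(-4, 4, by = 0.25)
  expect_equal(erf(-zs), -erf(zs))
  expect_true(all(erf(zs) > -1 & erf(zs) < 1))
  expect_true(all(diff(erf(zs)) > 0))
  expect_equal(erfinv(erf(zs)), zs, tolerance = 1e-9)
})

test_that("evaluate_profile reproduces closed-form cases", {
  # all shifts zero: every term vanishes at k = 0, leaving the offset
  m <- erf_sum(A = c(30, -12, 5), a = c(0, 0, 0), b = c(1, 2, 3), C0 = 50)
  expect_equal(evaluate_profile(m, 0), 50)
  # two opposed terms at +/- b: D(0) = 100 erf(1)
  b <- 1.7
  m2 <- erf_sum(A = c(50, -50), a = c(b, -b), b = c(b, b), C0 = 0)
  expect_equal(evaluate_profile(m2, 0), 100 * erf(1), tolerance = 1e-12)
  # single falling edge: limits 0 and 100
  m3 <- erf_sum(A = -50, a = 0, b = 2, C0 = 50)
  expect_equal(evaluate_profile(m3, 1e6), 0, tolerance = 1e-12)
  expect_equal(evaluate_profile(m3, -1e6), 100, tolerance = 1e-12)
})

test_that("symmetric models are exactly even; penumbra fixtures decrease in |k|", {
  m <- fixture_known_model(symmetric = TRUE)
  ks <- seq(0.1, 12, by = 0.37)
  expect_identical(evaluate_profile(m, ks), evaluate_profile(m, -ks))
  d <- evaluate_profile(m, seq(0, 12, by = 0.05))
  expect_true(all(diff(d) <= 0) && any(diff(d) < 0))
})

test_that("profile_curve validates its invariants", {
  expect_s3_class(profile_curve(0:10, rep(50, 11), "x", 16), "profile_curve")
  expect_error(profile_curve(c(0, 1, 1), c(1, 2, 3), "x", 16),
               "strictly increasing")
  expect_error(profile_curve(0:2, c(10, 200, 10), "x", 16), "\\[0, 110\\]")
  expect_error(profile_curve(0:2, c(10, 20), "x", 16), "same length")
})

test_that("noiseless round-trip fit recovers the sampled curve", {
  for (sym in c(TRUE, FALSE)) {
    m <- fixture_known_model(symmetric = sym)
    k <- seq(-12, 12, length.out = 50)
    curve <- profile_curve(k, evaluate_profile(m, k),
                           axis = if (sym) "x" else "z", field_size_mm = 8)
    ft <- fit_profile(curve, n = m$n, symmetric = sym, seed = 2)
    kk <- if (sym) k[k >= 0] else k
    expect_lt(max(abs(predict(ft, kk) - evaluate_profile(m, kk))), 1e-6)
    expect_gte(ft$r_squared, 0.999999)
    # same-n noiseless recovery: predictions, not parameters, must agree
    expect_lt(ft$residual_max, 1e-4)
  }
})

test_that("fits of noisy profiles stay in the R^2 >= 0.999 regime", {
  m <- fixture_known_model(symmetric = TRUE)
  k <- seq(0, 14, length.out = 120)
  set.seed(42)
  d <- pmin(pmax(evaluate_profile(m, k) + rnorm(120, sd = 0.2), 0), 110)
  ft <- fit_profile(profile_curve(k, d, "x", 8), n = 4, symmetric = TRUE,
                    seed = 3)
  expect_gte(ft$r_squared, 0.999)
})

test_that("degenerate zero-variance input is reported as a failed fit", {
  curve <- profile_curve(seq(0, 10), rep(80, 11), "x", 16)
  ft <- fit_profile(curve, n = 1, symmetric = TRUE)
  expect_false(ft$converged)
  expect_true(is.na(ft$r_squared))
  expect_match(ft$message, "zero-variance")
})

test_that("fit_profile enforces the minimum point count", {
  k <- seq(0, 5, length.out = 8)
  curve <- profile_curve(k, evaluate_profile(fixture_known_model(), k), "x", 16)
  expect_error(fit_profile(curve, n = 4, symmetric = TRUE), "at least")
})

test_that("erf_fit methods are coherent and model IO round-trips", {
  m <- fixture_known_model(symmetric = TRUE)
  k <- seq(0, 14, length.out = 60)
  ft <- fit_profile(profile_curve(k, evaluate_profile(m, k), "x", 8),
                    n = 2, symmetric = TRUE, seed = 4)
  expect_length(coef(ft), 3 * 2 + 1)
  expect_equal(residuals(ft),
               ft$data$dose_percent - predict(ft), tolerance = 1e-12)
  expect_equal(dim(simulate(ft, nsim = 3, seed = 1)), c(60L, 3L))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_erf_model(ft, path)
  m2 <- read_erf_model(path)
  expect_equal(evaluate_profile(m2, k), predict(ft, k), tolerance = 1e-9)
})

test_that("erf_sum rejects invalid parameters", {
  expect_error(erf_sum(A = 1, a = 0, b = 0), "strictly positive")
  expect_error(erf_sum(A = numeric(0), a = numeric(0), b = numeric(0)),
               "at least one")
  expect_error(erf_sum(A = c(1, 2), a = 0, b = c(1, 1)), "equal length")
})
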