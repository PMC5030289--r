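# An analytic stand-in forward model (diffusion-like exponential decay)
# exercises the fitting machinery without Monte Carlo cost; the Monte Carlo
# forward model is exercised in test-recovery.R.
analytic_forward <- function(radii = c(2, 5, 8, 11, 14, 17, 20)) {
  function(mu_a, mu_s_prime) {
    mu_eff <- sqrt(3 * mu_a * (mu_a + mu_s_prime))  # cm^-1
    r_cm <- radii / 10
    exp(-mu_eff * r_cm) / r_cm
  }
}

test_that("normalization fixes the reference to 1 and is scale invariant", {
  M <- measurement_series(rep(c(2, 5, 8), 2),
                          rep(c(4, 2, 1), 2) * rep(c(0.9, 1.1), each = 3),
                          replicate = rep(1:2, each = 3))
  Mn <- normalize_at_reference(M, 2)
  avg <- aggregate(signal_au ~ r_mm, as.data.frame(Mn), mean)
  expect_equal(avg$signal_au[avg$r_mm == 2], 1)
  # scale invariance
  M2 <- M; M2$signal_au <- 37 * M2$signal_au
  expect_equal(normalize_at_reference(M2, 2)$signal_au, Mn$signal_au)
  # idempotence
  expect_equal(normalize_at_reference(Mn, 2)$signal_au, Mn$signal_au)
  expect_error(normalize_at_reference(M, 25), "outside")
})

test_that("normalization interpolates log-linearly off the sample grid", {
  a <- 0.3
  pr <- structure(data.frame(r_mm = c(2, 5, 8), phi = exp(-a * c(2, 5, 8))),
                  class = c("radial_profile", "data.frame"))
  out <- normalize_at_reference(pr, 3.5)
  # under log-linear interpolation the implied reference is exp(-3.5a)
  expect_equal(out$phi, exp(-a * c(2, 5, 8)) / exp(-a * 3.5),
               tolerance = 1e-12)
})

test_that("profiled K is the exact least-squares scale", {
  set.seed(1)
  phi <- exp(-0.4 * c(2, 5, 8, 11)); m <- 3 * phi + rnorm(4, 0, 0.01)
  K <- sum(m * phi) / sum(phi^2)
  sse <- function(k) sum((m - k * phi)^2)
  expect_lt(sse(K), sse(K * 1.01))
  expect_lt(sse(K), sse(K * 0.99))
})

test_that("fit recovers the free parameter from a noiseless measurement", {
  # the analytic decay has a single shape parameter (mu_eff), so only one
  # optical parameter is identifiable from it; joint (mu_a, mu_s')
  # recovery is exercised against the Monte Carlo forward model in
  # test-recovery.R
  fw <- analytic_forward()
  M <- measurement_series(c(2, 5, 8, 11, 14, 17, 20), 5000 * fw(1.8, 10))
  fit <- fit_measurement(M, fw, free = "mu_s_prime",
                         init = list(mu_s_prime = 30),
                         fixed = list(mu_a = 1.8),
                         control = list(reltol = 1e-10, maxit = 500))
  expect_equal(fit$mu_s_prime, 10, tolerance = 1e-3)
  expect_equal(fit$K, 5000, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("rescaling the measurement rescales K but not the shape parameters", {
  fw <- analytic_forward()
  M1 <- measurement_series(c(2, 5, 8, 11, 14, 17, 20), 100 * fw(0.5, 5))
  M2 <- M1; M2$signal_au <- 7 * M2$signal_au
  f1 <- fit_measurement(M1, fw, free = "mu_s_prime",
                        init = list(mu_s_prime = 8), fixed = list(mu_a = 0.5))
  f2 <- fit_measurement(M2, fw, free = "mu_s_prime",
                        init = list(mu_s_prime = 8), fixed = list(mu_a = 0.5))
  expect_equal(f2$K / f1$K, 7, tolerance = 1e-6)
  expect_equal(f2$mu_s_prime, f1$mu_s_prime, tolerance = 1e-6)
})

test_that("perturbed simplex starts converge to the same optimum", {
  fw <- analytic_forward()
  M <- measurement_series(c(2, 5, 8, 11, 14, 17, 20), 42 * fw(0.01, 3.4))
  fits <- lapply(c(0.5, 1, 1.5) * 3.4, function(init)
    fit_measurement(M, fw, free = "mu_s_prime",
                    init = list(mu_s_prime = init),
                    fixed = list(mu_a = 0.01),
                    control = list(reltol = 1e-8, maxit = 500)))
  vals <- vapply(fits, `[[`, 0, "mu_s_prime")
  expect_lt(diff(range(vals)) / median(vals), 0.02)
})

test_that("calibration maps the measurement back onto the model fluence", {
  fw <- analytic_forward()
  K0 <- 1234
  M <- measurement_series(c(2, 5, 8, 11, 14, 17, 20), K0 * fw(1.8, 10))
  fit <- fit_measurement(M, fw, free = "mu_s_prime",
                         init = list(mu_s_prime = 9),
                         fixed = list(mu_a = 1.8),
                         control = list(reltol = 1e-10, maxit = 500))
  cal <- calibrate_measurement(M, fit)
  expect_equal(cal$phi, fw(1.8, 10), tolerance = 1e-3)  # round-trip overlay
  # at the reference radius, CALIB * M(2) equals the model fluence there
  expect_equal(cal$phi[cal$r_mm == 2], fit$calib * fit$M_ref,
               tolerance = 1e-12)
  expect_error(calibrate_measurement(
    measurement_series(c(5, 8), c(1, 1)), fit), "reference")
})

test_that("lookup table stores one profile per grid point and flags holes", {
  fw <- analytic_forward(c(2, 5, 8))
  tab <- build_lookup_table(fw, c(0.1, 1), c(1, 10, 100), c(2, 5, 8))
  expect_identical(dim(tab$entries), c(2L, 3L, 3L))
  expect_false(any(tab$holes))
  expect_equal(tab$entries[2, 2, ], fw(1, 10))
  # a failing forward evaluation leaves a flagged hole, table still usable
  fw_bad <- function(mu_a, mu_s_prime) {
    if (mu_s_prime > 50) stop("boom") else fw(mu_a, mu_s_prime)
  }
  tab2 <- build_lookup_table(fw_bad, c(0.1), c(1, 100), c(2, 5, 8))
  expect_true(tab2$holes[1, 2])
  expect_false(tab2$holes[1, 1])
  expect_equal(tab2$entries[1, 1, ], fw(0.1, 1))
})

test_that("normalized lookup profiles steepen monotonically with mu_s'", {
  # Monte Carlo forward model on the bare skeleton: the decay slope of
  # ln phi(r) must become increasingly negative as mu_s' grows
  fw <- skeleton_forward_provider(params = small_measure_params(),
                                  radii = small_radii,
                                  n_photons = 3e4, seed = 31)
  slopes <- vapply(c(1.7, 3.4, 6.8), function(ms) {
    phi <- fw(0.01, ms)
    unname(coef(lm(log(phi) ~ small_radii))[2])
  }, 0)
  expect_true(all(diff(slopes) < 0))
})
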