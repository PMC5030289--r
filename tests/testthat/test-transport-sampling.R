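test_that("step-length sampling matches the exponential free-path law", {
  expect_equal(sample_step_length(exp(-1), 1), 1)
  # ln2 / mu_t with the coral-tissue total interaction coefficient
  expect_equal(sample_step_length(0.5, 101.8), log(2) / 101.8,
               tolerance = 1e-12)
  expect_error(sample_step_length(0, 1), "u must")
  expect_error(sample_step_length(0.5, 0), "mu_t")

  set.seed(42)
  for (mu_t in c(1, 34, 101.8)) {
    s <- sample_step_length(runif(1e5), mu_t)
    se <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - 1 / mu_t), 3 * se)
  }
})

test_that("Henyey-Greenstein sampling has the correct form and first moment", {
  expect_equal(sample_hg_deflection(0.25, 0), -0.5)  # isotropic
  # closed-form inverse CDF at g = 0.9, u = 0.5:
  # f = (1-g^2)/(1-g+2gu) = 0.19; cos = (1+g^2-f^2)/(2g)
  expect_equal(sample_hg_deflection(0.5, 0.9),
               (1 + 0.81 - 0.19^2) / 1.8, tolerance = 1e-12)
  expect_equal(round(sample_hg_deflection(0.5, 0.9), 5), 0.98550)
  expect_error(sample_hg_deflection(0.5, 1), "< 1")

  set.seed(7)
  for (g in c(0, 0.5, 0.9)) {
    ct <- sample_hg_deflection(runif(1e6), g)
    expect_true(all(ct >= -1 & ct <= 1))
    se <- sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se)  # first moment of HG equals g
  }
})

test_that("direction update preserves the unit norm and the deflection angle", {
  expect_equal(update_direction(c(0, 0, 1), 1, 0.3), c(0, 0, 1))
  # 90-degree deflection from vertical is perpendicular
  out <- update_direction(c(0, 0, 1), 0, 0)
  expect_lt(abs(sum(out * c(0, 0, 1))), 1e-9)
  expect_equal(sum(out^2), 1, tolerance = 1e-9)

  set.seed(11)
  for (i in 1:500) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    ct <- runif(1, -1, 1); psi <- runif(1, 0, 2 * pi)
    w <- update_direction(v, ct, psi)
    expect_lt(abs(sum(w^2) - 1), 1e-9)
    expect_lt(abs(sum(v * w) - ct), 1e-9)
  }
})

test_that("Russian roulette is unbiased and leaves large weights alone", {
  expect_equal(roulette_weight(0.5, 0.99), 0.5)
  expect_equal(roulette_weight(1e-5, 0.05, threshold = 1e-4, m = 10), 1e-4)
  expect_equal(roulette_weight(1e-5, 0.5, threshold = 1e-4, m = 10), 0)

  set.seed(3)
  u <- runif(1e5)
  w <- vapply(u, function(ui) roulette_weight(2e-5, ui), 0)
  se <- sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - 2e-5), 3 * se)
})
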