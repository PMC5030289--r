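test_that("energy ledger closes exactly and results are deterministic", {
  p <- slab_params()
  g <- build_homogeneous_slab(make_medium(1, 10), 8, p)
  r1 <- propagate(g, source_spec("pencil"), n_photons = 5e3, seed = 99)
  r2 <- propagate(g, source_spec("pencil"), n_photons = 5e3, seed = 99)
  r3 <- propagate(g, source_spec("pencil"), n_photons = 5e3, seed = 100)

  expect_lt(abs(sum(r1$ledger[-1]) - 1), 1e-6)
  expect_true(all(r1$fluence >= 0))
  expect_true(all(r1$escape >= 0))
  expect_identical(r1$fluence, r2$fluence)   # bit-identical reproduction
  expect_identical(r1$ledger, r2$ledger)
  expect_false(identical(r1$fluence, r3$fluence))
})

test_that("ledger closes across source kinds and media mixes", {
  p <- slab_params()
  for (src in list(source_spec("pencil"),
                   source_spec("disk", diameter = 2.05),
                   source_spec("plane", zenith_deg = 45))) {
    g <- build_homogeneous_slab(make_medium(0.3, 5), 8, p)
    r <- propagate(g, src, n_photons = 5e3, seed = 4)
    expect_lt(abs(sum(r$ledger[-1]) - 1), 1e-6)
  }
  # two-layer coral geometry
  gc <- build_coral_model(small_coral_params())
  rc <- propagate(gc, laser(), n_photons = 5e3, seed = 4)
  expect_lt(abs(sum(rc$ledger[-1]) - 1), 1e-6)
})

test_that("pure absorber follows Beer-Lambert attenuation with depth", {
  p <- slab_params()
  mu_a <- 15
  g <- build_homogeneous_slab(make_medium(mu_a, 0, g = 0), 10, p)
  r <- propagate(g, source_spec("pencil"), n_photons = 8e4, seed = 21)
  ax <- axial_profile(r, 0, 0)
  keep <- ax$phi > 0 & ax$z_mm < 4
  fit <- lm(log(phi) ~ z_mm, data = ax[keep, ])
  expect_gt(summary(fit)$r.squared, 0.999)
  # slope in cm^-1 equals -mu_a
  expect_equal(unname(coef(fit)[2]) * 10, -mu_a, tolerance = 0.05)
  # no backscatter in a pure absorber: monotone decay over the
  # well-sampled depths
  mono <- ax$phi > 0 & ax$z_mm < 3
  expect_true(all(diff(ax$phi[mono]) < 0))
})

test_that("radial profile peaks under the beam and decays monotonically", {
  p <- slab_params()
  g <- build_homogeneous_slab(make_medium(0.5, 10), 10, p)
  r <- propagate(g, source_spec("disk", diameter = 2.05), 4e4, seed = 5)
  pr <- surface_radial_profile(r, radii = c(0, 2, 3.5, 5, 6.5),
                               mode = "annulus", band_r = 0.5)
  expect_equal(which.max(pr$phi), 1L)  # maximum at the beam center
  beyond <- pr$r_mm >= 2               # beyond the beam edge
  expect_true(all(diff(pr$phi[beyond]) < 0))
  expect_error(surface_radial_profile(r, radii = c(2, 50)), "domain")
})

test_that("profile estimator is consistent when doubling the photon count", {
  p <- slab_params()
  g <- build_homogeneous_slab(make_medium(0.5, 10), 10, p)
  radii <- c(1, 2, 3, 4)
  r1 <- propagate(g, source_spec("disk"), 3e4, seed = 6)
  r2 <- propagate(g, source_spec("disk"), 6e4, seed = 7)
  p1 <- surface_radial_profile(r1, radii, mode = "annulus")$phi
  p2 <- surface_radial_profile(r2, radii, mode = "annulus")$phi
  expect_true(all(abs(p1 - p2) / p2 < 0.15))
})

test_that("mirrored oblique illumination mirrors the fluence map", {
  p <- slab_params()
  g <- build_homogeneous_slab(make_medium(0.5, 10), 10, p)
  rp <- propagate(g, source_spec("disk", zenith_deg = 30), 3e4, seed = 8)
  rm <- propagate(g, source_spec("disk", zenith_deg = -30), 3e4, seed = 8)
  d <- dim(rp$fluence)
  half <- seq_len(d[1] %/% 2 - 2)            # skip the central columns
  lo_p <- sum(rp$fluence[half, , ]); hi_p <- sum(rp$fluence[d[1] + 1 - half, , ])
  lo_m <- sum(rm$fluence[half, , ]); hi_m <- sum(rm$fluence[d[1] + 1 - half, , ])
  # the beam tilts toward +x: the heavy half swaps sides under mirroring
  expect_gt(hi_p, lo_p)
  expect_gt(lo_m, hi_m)
  expect_lt(abs(hi_p - lo_m) / hi_p, 0.05)
  expect_lt(abs(lo_p - hi_m) / lo_p, 0.05)
})

test_that("axial profile reports the requested column and validates input", {
  p <- slab_params()
  g <- build_homogeneous_slab(make_medium(1, 5), 8, p)
  r <- propagate(g, source_spec("pencil"), 1e4, seed = 2)
  ax <- axial_profile(r, 0, 0)
  expect_identical(nrow(ax), dim(r$fluence)[3])
  expect_error(axial_profile(r, 100, 0), "domain")
})
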