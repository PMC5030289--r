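# Coarse, fast settings: these tests check structure and qualitative
# physics; the quantitative enhancement figures run in test-acceptance.R.
coarse_exp_params <- function() {
  coral_model_params(domain_x = 26, domain_y = 10, domain_z = 14,
                     dx = 0.25, dy = 0.25, dz = 0.1, water_depth = 1)
}

test_that("vertical sun enhances fluence inside the tissue layer", {
  rep <- run_vertical_sun(params = coarse_exp_params(),
                          n_photons = 6e4, seed = 13)
  expect_lt(abs(sum(rep$ledger[-1]) - 1), 1e-6)
  # the fluence maximum sits inside the tissue, not in water or skeleton
  expect_gte(rep$depth_of_max_um, 0)
  expect_lt(rep$depth_of_max_um, 2000)
  # scattering builds the in-tissue fluence above the incident irradiance
  expect_gt(rep$max_tissue_enh, 1)
  # backscatter adds to the downwelling beam in the water column
  expect_gt(rep$max_water_enh, 1)
  expect_lt(rep$max_water_enh, rep$max_tissue_enh)
})

test_that("depth attenuation is slower in skeleton than in tissue", {
  rep <- run_vertical_sun(params = coarse_exp_params(),
                          n_photons = 6e4, seed = 13)
  ax <- rep$axial
  p <- coarse_exp_params()
  zs <- p$water_depth; zc <- zs + p$tissue_thickness
  tis <- ax$z_mm > zs + 0.4 & ax$z_mm < zc
  skel <- ax$z_mm > zc + 1 & ax$z_mm < zc + 6
  slope <- function(sel) unname(coef(lm(log(ax$phi[sel]) ~ ax$z_mm[sel]))[2])
  expect_gt(abs(slope(tis)), abs(slope(skel)))
})

test_that("oblique sun report isolates the shaded far-wall tissue", {
  rep <- run_oblique_sun(params = coarse_exp_params(), angle = 45,
                         n_photons = 6e4, seed = 17)
  expect_lt(abs(sum(rep$ledger[-1]) - 1), 1e-6)
  expect_gt(rep$n_shaded_voxels, 0)
  expect_gt(rep$far_wall_enh, 0)
  # shaded-side tissue sees far less light than the direct-beam maximum
  expect_lt(rep$far_wall_enh, 1)
})

test_that("absorption sensitivity report has power to detect strong absorbers", {
  sens <- skeleton_absorption_sensitivity(
    mu_a_values = c(0.01, 10), mu_s_prime = 3.4,
    params = small_measure_params(), radii = small_radii,
    n_photons = 4e4, seed = 23)
  expect_identical(dim(sens$profiles), c(length(small_radii), 2L))
  # profiles are normalized at the 2 mm reference
  expect_equal(unname(sens$profiles[1, ]), c(1, 1))
  # a 1000x increase in absorption must visibly steepen the decay
  expect_gt(sens$max_pairwise_dev, 0.3)
})
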