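test_that("coral model layers probe correctly at characteristic positions", {
  p <- small_coral_params()
  g <- build_coral_model(p)

  # wall center: tissue for the first 2 mm below the surface, skeleton below
  zs <- p$water_depth
  for (z in zs + c(0.2, 1.0, 1.8))
    expect_identical(grid_label_at(g, 0, 0, z), "tissue")
  expect_identical(grid_label_at(g, 0, 0, zs + p$tissue_thickness + 5),
                   "skeleton")
  # water above the colony
  expect_identical(grid_label_at(g, 0, 0, zs / 2), "water")
  # corallite center above the tissue lining: water fills the cup
  xc <- (p$wall_thickness + p$corallite_width) / 2
  expect_identical(grid_label_at(g, xc, 0, zs + 3), "water")
  # cup floor lining is tissue, solid base below is skeleton
  zfloor <- zs + p$tissue_thickness + p$corallite_depth
  expect_identical(grid_label_at(g, xc, 0, zfloor - 0.5), "tissue")
  expect_identical(grid_label_at(g, xc, 0, zfloor + 1), "skeleton")
})

test_that("coral model has three media and is extruded along y", {
  g <- build_coral_model(small_coral_params())
  expect_setequal(unique(as.vector(g$labels)), 1:3)
  expect_identical(names(g$media), c("water", "tissue", "skeleton"))
  ny <- dim(g$labels)[2]
  for (j in c(2, ny %/% 2, ny))
    expect_identical(g$labels[, j, ], g$labels[, 1, ])
})

test_that("tissue layer thickness at the wall crest matches within one voxel", {
  p <- small_coral_params()
  g <- build_coral_model(p)
  i <- floor((0 - g$origin_mm[1]) / p$dx) + 1
  n_tissue <- sum(g$labels[i, 1, ] == 2L)
  expect_lte(abs(n_tissue * p$dz - p$tissue_thickness), p$dz)
})

test_that("bare skeleton removes tissue only, conserving skeleton voxels", {
  p <- small_coral_params()
  coral <- build_coral_model(p)
  bare <- build_bare_skeleton(p)
  expect_identical(sum(bare$labels == 3L), sum(coral$labels == 3L))
  expect_identical(sum(bare$labels == 2L), 0L)
  # every voxel that was tissue is now water
  expect_true(all(bare$labels[coral$labels == 2L] == 1L))
  # skeleton voxels in identical positions
  expect_identical(bare$labels == 3L, coral$labels == 3L)
})

test_that("replace_skeleton_with_tissue swaps media only and is idempotent", {
  g <- build_coral_model(small_coral_params())
  tis <- g$media$tissue
  g2 <- replace_skeleton_with_tissue(g, tis)
  expect_identical(g2$labels, g$labels)
  expect_identical(g2$media$skeleton, tis)
  expect_identical(replace_skeleton_with_tissue(g2, tis), g2)
  # a grid without skeleton is rejected
  slab <- build_homogeneous_slab(make_medium(1, 1), 5, slab_params())
  expect_error(replace_skeleton_with_tissue(slab, tis), "skeleton")
})

test_that("homogeneous slab builder validates and places the slab", {
  p <- slab_params()
  expect_error(build_homogeneous_slab(make_medium(1, 1), 0, p),
               "thickness")
  g <- build_homogeneous_slab(make_medium(5, 0, g = 0), 5, p)
  expect_identical(grid_label_at(g, 0, 0, 2), "slab")
  expect_identical(grid_label_at(g, 0, 0, 8), "water")
})

test_that("model parameter validation rejects unresolvable voxels", {
  expect_error(coral_model_params(dx = 0.6), "unresolved")
  expect_error(coral_model_params(dz = 0.7), "unresolved")
  expect_error(coral_model_params(tissue_thickness = 9), "corallite_depth")
  expect_error(coral_model_params(wall_thickness = -1), "> 0")
  expect_error(coral_model_params(domain_x = 10), "domain_x")
})
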