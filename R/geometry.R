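#' Parameters of the simplified two-layer coral model
#'
#' Holds the dimensions of the voxelized faviid coral model: a periodic
#' array of skeletal walls (coenosteum) separating corallite cups, with a
#' living tissue layer draped conformally over the wall crests and cup
#' interiors, all under a water column. The cross-section is drawn in x
#' (length) vs z (depth, increasing downward from the top of the water
#' column) and extruded unchanged along y (width).
#'
#' Defaults describe a massive faviid coral: 3 mm thick walls, 10 mm wide
#' and 8 mm deep corallites, 2 mm thick tissue. The default domain
#' (26 x 54 x 20 mm) holds one full corallite on each side of a central
#' wall plus flanking half-walls in x, extends far enough along the wall
#' axis (y) to contain radial measurements out to 20 mm, and keeps several
#' transport mean free paths of solid skeletal base below the cup floors.
#' Default voxels (0.25 x 0.25 x 0.125 mm) resolve the tissue layer at 16
#' voxels in depth; illumination experiments use finer grids (see
#' [experiment_params()]).
#'
#' @param wall_thickness Coenosteum wall thickness \[mm\].
#' @param corallite_width Corallite cup width \[mm\].
#' @param corallite_depth Corallite cup depth below the wall crest \[mm\].
#' @param tissue_thickness Living tissue layer thickness \[mm\].
#' @param domain_x,domain_y,domain_z Domain extents \[mm\].
#' @param dx,dy,dz Voxel sizes \[mm\]. Rejected if coarser than
#'   `tissue_thickness / 4` (the tissue layer would be unresolved).
#' @param water_depth Water column above the tissue surface at the wall
#'   crest \[mm\].
#' @return A `coral_model_params` list.
#' @export
coral_model_params <- function(wall_thickness = 3, corallite_width = 10,
                               corallite_depth = 8, tissue_thickness = 2,
                               domain_x = 26, domain_y = 54, domain_z = 20,
                               dx = 0.25, dy = 0.25, dz = 0.125,
                               water_depth = 1) {
  p <- list(wall_thickness = wall_thickness, corallite_width = corallite_width,
            corallite_depth = corallite_depth,
            tissue_thickness = tissue_thickness,
            domain_x = domain_x, domain_y = domain_y, domain_z = domain_z,
            dx = dx, dy = dy, dz = dz, water_depth = water_depth)
  lens <- unlist(p)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all model lengths must be finite and > 0")
  if (tissue_thickness >= corallite_depth)
    stop("tissue_thickness must be smaller than corallite_depth")
  if (max(dx, dy, dz) > tissue_thickness / 4)
    stop("voxel size coarser than tissue_thickness/4: tissue layer unresolved")
  if (domain_x < corallite_width + 2 * wall_thickness)
    stop("domain_x too small to contain one corallite plus flanking walls")
  if (domain_z < water_depth + tissue_thickness + corallite_depth)
    stop("domain_z too shallow for the corallite cup")
  structure(p, class = "coral_model_params")
}

# x positions are classified against a periodic wall/corallite pattern with
# a wall centered at x = 0; returns horizontal distance [mm] from each x to
# the nearest wall interval (0 inside a wall).
wall_distance <- function(x, wall_thickness, corallite_width) {
  period <- wall_thickness + corallite_width
  # fold into one period centered on a wall
  u <- (x + wall_thickness / 2) %% period
  d <- pmin(pmax(u - wall_thickness, 0), pmax(period - u, 0))
  d[u <= wall_thickness] <- 0
  d
}

# Label one x-z cross-section. 1 = water, 2 = tissue, 3 = skeleton.
# The tissue is the conformal dilation of the skeleton surface by
# tissue_thickness (Euclidean distance), which drapes the wall crest, cup
# sides and cup floor with a uniform layer (rounded at convex corners).
coral_slice <- function(p) {
  nx <- round(p$domain_x / p$dx)
  nz <- round(p$domain_z / p$dz)
  xc <- (seq_len(nx) - 0.5) * p$dx - p$domain_x / 2
  zc <- (seq_len(nz) - 0.5) * p$dz
  zs <- p$water_depth                        # tissue surface at the crest
  zcrest <- zs + p$tissue_thickness          # skeleton top of the wall
  zfloor <- zcrest + p$corallite_depth       # skeleton top of the cup floor

  dwx <- wall_distance(xc, p$wall_thickness, p$corallite_width)
  lab <- matrix(1L, nx, nz)
  for (j in seq_len(nz)) {
    z <- zc[j]
    in_skel <- (dwx == 0 & z >= zcrest) | (z >= zfloor)
    # distance to the wall (side face below the crest, corner-rounded above)
    d_wall <- if (z >= zcrest) dwx else sqrt(dwx^2 + (zcrest - z)^2)
    d_floor <- zfloor - z
    d <- pmin(d_wall, d_floor)
    col <- ifelse(in_skel, 3L, ifelse(d <= p$tissue_thickness, 2L, 1L))
    lab[, j] <- col
  }
  lab
}

new_voxel_grid <- function(labels, media, p) {
  structure(
    list(labels = labels, media = media,
         voxel_mm = c(p$dx, p$dy, p$dz),
         origin_mm = c(-p$domain_x / 2, -p$domain_y / 2, 0),
         params = p),
    class = "voxel_grid"
  )
}

#' Build the voxelized two-layer coral model
#'
#' Constructs a labeled voxel grid with three media: water above and inside
#' the corallite cups, a conformal living tissue layer, and the aragonite
#' skeleton (walls, cup floors and solid base). Every x-z slice is
#' identical along y (extruded geometry).
#'
#' @param params A [coral_model_params()] object.
#' @param tissue,skeleton,water [make_medium()] objects for the three media.
#' @return A `voxel_grid`: integer label array (`1` water, `2` tissue,
#'   `3` skeleton), the media table, voxel sizes and origin \[mm\].
#' @export
build_coral_model <- function(params,
                              tissue = make_medium(1.8, 10),
                              skeleton = make_medium(0.01, 3.4),
                              water = water_medium()) {
  stopifnot(inherits(params, "coral_model_params"))
  slab <- coral_slice(params)
  ny <- round(params$domain_y / params$dy)
  labels <- aperm(array(slab, dim = c(nrow(slab), ncol(slab), ny)),
                  c(1L, 3L, 2L))
  new_voxel_grid(labels,
                 list(water = water, tissue = tissue, skeleton = skeleton),
                 params)
}

#' Build the bare-skeleton model (tissue removed)
#'
#' Same geometry as [build_coral_model()] but with every tissue voxel
#' relabeled to water, emulating the measurement repeated on the air-gun
#' cleaned skeleton under otherwise identical underwater conditions.
#' Skeleton voxels are untouched.
#'
#' @inheritParams build_coral_model
#' @return A `voxel_grid` with media water and skeleton (the tissue label is
#'   retained in the media table but no voxel carries it).
#' @export
build_bare_skeleton <- function(params,
                                skeleton = make_medium(0.01, 3.4),
                                water = water_medium()) {
  g <- build_coral_model(params, tissue = water, skeleton = skeleton,
                         water = water)
  g$labels[g$labels == 2L] <- 1L
  g$media$tissue <- water
  g
}

#' Replace the skeleton's optical properties with tissue properties
#'
#' Returns a grid with identical geometry (the label array is untouched)
#' whose skeleton label now maps to the given tissue optical properties, as
#' if the colony were a solid mass of living tissue. Used to isolate the
#' skeleton's role in trans-skeletal light transport. Idempotent.
#'
#' @param grid A `voxel_grid` containing skeleton voxels.
#' @param tissue An [make_medium()] object to assign to the skeleton label.
#' @return The modified `voxel_grid`.
#' @export
replace_skeleton_with_tissue <- function(grid, tissue) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!any(grid$labels == 3L)) stop("grid contains no skeleton voxels")
  grid$media$skeleton <- tissue
  grid
}

#' Homogeneous slab geometry for closed-form validation
#'
#' A single participating medium occupying depths `z` in
#' \[`water_depth`, `water_depth + thickness`) with water above and below
#' (or filling the rest of the domain). Used by the validation suite
#' (Beer-Lambert attenuation, diffusion-theory decay, diffuse-reflectance
#' benchmarks); set `water_depth = 0` and `thickness = domain_z` for a
#' semi-infinite medium flush with the top boundary.
#'
#' @param props [make_medium()] object for the slab.
#' @param thickness Slab thickness \[mm\], > 0.
#' @param params A [coral_model_params()] (only domain/voxel/water fields
#'   are used).
#' @param water Medium for the non-slab voxels.
#' @return A `voxel_grid` with labels `1` (water) and `2` (slab).
#' @export
build_homogeneous_slab <- function(props, thickness, params,
                                   water = water_medium()) {
  stopifnot(inherits(params, "coral_model_params"))
  if (!is.numeric(thickness) || thickness <= 0)
    stop("thickness must be > 0")
  nx <- round(params$domain_x / params$dx)
  ny <- round(params$domain_y / params$dy)
  nz <- round(params$domain_z / params$dz)
  zc <- (seq_len(nz) - 0.5) * params$dz
  in_slab <- zc >= params$water_depth &
    zc < params$water_depth + thickness
  labels <- array(1L, dim = c(nx, ny, nz))
  labels[, , in_slab] <- 2L
  new_voxel_grid(labels, list(water = water, slab = props), params)
}

#' Seawater as a weakly participating medium
#'
#' Water voxels must accumulate fluence (the illumination experiments report
#' light enhancement in the water above the tissue), so water is modeled as
#' a very weak absorber/scatterer near its red-wavelength optics rather than
#' as vacuum. The values are small enough not to influence in-tissue
#' results over the centimeter scales simulated.
#'
#' @param mu_a,mu_s_prime,g,n Optical properties; defaults are for 636 nm.
#' @return An `optical_medium`.
#' @export
water_medium <- function(mu_a = 0.003, mu_s_prime = 0.05, g = 0.9, n = 1.33) {
  make_medium(mu_a, mu_s_prime, g = g, n = n)
}

#' Look up the medium label at a physical position
#'
#' @param grid A `voxel_grid`.
#' @param x,y,z Position \[mm\] (z measured down from the top of the water
#'   column).
#' @return The medium name (`"water"`, `"tissue"`, `"skeleton"`, ...).
#' @export
grid_label_at <- function(grid, x, y, z) {
  stopifnot(inherits(grid, "voxel_grid"))
  i <- voxel_index(grid, x, y, z)
  names(grid$media)[grid$labels[i[1], i[2], i[3]]]
}

voxel_index <- function(grid, x, y, z) {
  d <- dim(grid$labels)
  i <- floor((c(x, y, z) - grid$origin_mm) / grid$voxel_mm) + 1
  if (any(i < 1) || any(i > d)) stop("position outside the voxel domain")
  as.integer(i)
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (%g x %g x %g mm)\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  tab <- table(factor(x$labels, levels = seq_along(x$media),
                      labels = names(x$media)))
  cat("  media:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a voxel grid to plain-text files
#'
#' Serializes the label array as a TSV stack (one block of rows per z slice)
#' plus a sidecar media table (`<stem>_media.csv` with columns label, name,
#' mu_a, mu_s, g, n). Intended for interchange and inspection, not speed.
#'
#' @param grid A `voxel_grid`.
#' @param stem Output path stem (files `<stem>_labels.tsv`,
#'   `<stem>_media.csv`).
#' @return Invisibly, the two file paths.
#' @export
write_voxel_grid <- function(grid, stem) {
  stopifnot(inherits(grid, "voxel_grid"))
  lab_path <- paste0(stem, "_labels.tsv")
  med_path <- paste0(stem, "_media.csv")
  d <- dim(grid$labels)
  con <- file(lab_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims %d %d %d voxel_mm %g %g %g origin_mm %g %g %g",
                     d[1], d[2], d[3],
                     grid$voxel_mm[1], grid$voxel_mm[2], grid$voxel_mm[3],
                     grid$origin_mm[1], grid$origin_mm[2], grid$origin_mm[3]),
             con)
  for (k in seq_len(d[3])) {
    write.table(grid$labels[, , k], con, row.names = FALSE,
                col.names = FALSE, sep = "\t")
  }
  med <- data.frame(
    label = seq_along(grid$media), name = names(grid$media),
    mu_a = vapply(grid$media, `[[`, 0, "mu_a"),
    mu_s = vapply(grid$media, `[[`, 0, "mu_s"),
    g = vapply(grid$media, `[[`, 0, "g"),
    n = vapply(grid$media, `[[`, 0, "n"))
  write.csv(med, med_path, row.names = FALSE)
  invisible(c(lab_path, med_path))
}
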