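#' Specify a light source
#'
#' @param kind `"pencil"` (infinitesimal beam), `"disk"` (collimated
#'   circular beam of the given diameter) or `"plane"` (collimated plane
#'   wave covering the whole top face, for sun-like illumination).
#' @param x,y Beam center \[mm\] at the top of the domain (ignored for
#'   `"plane"`).
#' @param zenith_deg Zenith angle from vertical \[degrees\], in (-90, 90);
#'   positive tilts the beam toward +x.
#' @param diameter Beam diameter \[mm\] for `"disk"`; the laser used for the
#'   microprobe measurements had a 2.05 mm beam.
#' @param profile `"gaussian"` (1/e^2 diameter equal to `diameter`) or
#'   `"flat"` radial profile for `"disk"`.
#' @return A `source_spec` list.
#' @export
source_spec <- function(kind = c("disk", "pencil", "plane"),
                        x = 0, y = 0, zenith_deg = 0,
                        diameter = 2.05,
                        profile = c("gaussian", "flat")) {
  kind <- match.arg(kind)
  profile <- match.arg(profile)
  if (kind == "disk" && diameter <= 0) stop("diameter must be > 0")
  if (abs(zenith_deg) >= 90) stop("zenith angle must be inside (-90, 90)")
  structure(list(kind = kind, x = x, y = y, zenith_deg = zenith_deg,
                 diameter = diameter, profile = profile),
            class = "source_spec")
}

#' Sample an exponential free path
#'
#' Inverse-CDF sampling of the photon step length between interactions,
#' `s = -log(u) / mu_t`, whose expectation is the mean free path `1/mu_t`.
#'
#' @param u Uniform deviates in (0, 1\].
#' @param mu_t Total interaction coefficient \[cm^-1\], > 0.
#' @return Step lengths \[cm\].
#' @export
sample_step_length <- function(u, mu_t) {
  if (!is.numeric(mu_t) || any(mu_t <= 0)) stop("mu_t must be > 0")
  if (any(u <= 0) || any(u > 1)) stop("u must be in (0, 1]")
  -log(u) / mu_t
}

#' Sample a Henyey-Greenstein scattering deflection
#'
#' Inverse-CDF sampling of the deflection cosine from the
#' Henyey-Greenstein phase function with anisotropy `g`; the first moment
#' of the returned cosines equals `g`. For `g = 0` the deflection is
#' isotropic, `cos(theta) = 2u - 1`.
#'
#' @param u Uniform deviates in \[0, 1).
#' @param g Anisotropy, |g| < 1.
#' @return Deflection cosines in \[-1, 1\].
#' @export
sample_hg_deflection <- function(u, g) {
  if (abs(g) >= 1) stop("|g| must be < 1")
  if (abs(g) < 1e-6) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(pmax((1 + g^2 - f^2) / (2 * g), -1), 1)
}

#' Rotate a direction by a deflection cosine and azimuth
#'
#' Standard direction-cosine update used in the scattering spin step: the
#' output is a unit vector whose angle with the input has cosine
#' `cos_theta`, rotated by azimuth `psi` about the input direction. The
#' near-vertical case |uz| ~ 1 is handled separately.
#'
#' @param direction Unit 3-vector (ux, uy, uz).
#' @param cos_theta Deflection cosine in \[-1, 1\].
#' @param psi Azimuth \[radians\] in \[0, 2*pi).
#' @return The new unit direction.
#' @export
update_direction <- function(direction, cos_theta, psi) {
  u <- direction
  stopifnot(length(u) == 3, abs(sum(u^2) - 1) < 1e-6)
  ct <- cos_theta
  st <- sqrt(pmax(1 - ct^2, 0))
  if (abs(u[3]) > 0.99999) {
    out <- c(st * cos(psi), st * sin(psi), sign(u[3]) * ct)
  } else {
    den <- sqrt(1 - u[3]^2)
    out <- c(
      st * (u[1] * u[3] * cos(psi) - u[2] * sin(psi)) / den + u[1] * ct,
      st * (u[2] * u[3] * cos(psi) + u[1] * sin(psi)) / den + u[2] * ct,
      -st * cos(psi) * den + u[3] * ct)
  }
  out / sqrt(sum(out^2))
}

#' Russian roulette weight termination
#'
#' Unbiased termination of low-weight photon packets: a weight below
#' `threshold` survives with probability `1/m` at weight `m * W`, and is
#' terminated otherwise. The expectation of the returned weight equals the
#' input weight.
#'
#' @param W Photon weight.
#' @param u Uniform deviate in \[0, 1).
#' @param threshold Weight below which roulette is played.
#' @param m Roulette multiplier (> 1).
#' @return The surviving weight (possibly 0).
#' @export
roulette_weight <- function(W, u, threshold = 1e-4, m = 10) {
  stopifnot(threshold > 0, m > 1)
  if (W >= threshold) return(W)
  if (u < 1 / m) m * W else 0
}

#' Run the Monte Carlo photon transport simulation
#'
#' Launches `n_photons` weighted photon packets from `source` into `grid`
#' and accumulates the fluence rate per voxel with a track-length
#' estimator, the escape irradiance through the top boundary, and an exact
#' energy ledger. Refractive indices are treated as matched everywhere (no
#' Fresnel reflection); photons crossing the top boundary upward are scored
#' as escaped (and mapped), photons leaving through lateral or bottom faces
#' are scored as escaped without mapping. Weight is terminated by Russian
#' roulette, with terminated weight and roulette bonuses tracked in the
#' ledger residual so that `absorbed + escaped + residual = 1` to machine
#' precision.
#'
#' Identical `(grid, source, n_photons, seed)` reproduce bit-identical
#' results: every photon index owns an independent, deterministically
#' seeded random stream.
#'
#' @param grid A `voxel_grid`.
#' @param source A [source_spec()].
#' @param n_photons Number of photon packets (>= 1).
#' @param seed Integer seed for the photon streams.
#' @param roulette_threshold,roulette_m Roulette weight threshold and
#'   multiplier.
#' @return A `simulation_result` with elements `fluence` (3-D array, W cm^-2
#'   per W delivered), `escape` (top-boundary map, W cm^-2 per W delivered),
#'   `ledger` (fractions `absorbed`, `escaped`, `residual`, `launched`),
#'   `grid`, `n_photons`, `seed`.
#' @export
propagate <- function(grid, source, n_photons = 1e5, seed = 1,
                      roulette_threshold = 1e-4, roulette_m = 10) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(source, "source_spec"))
  if (n_photons < 1) stop("n_photons must be >= 1")
  rng_lab <- range(grid$labels)
  if (rng_lab[1] < 1L || rng_lab[2] > length(grid$media))
    stop("grid contains labels without an entry in the media table")
  d <- dim(grid$labels)
  vox_cm <- grid$voxel_mm / 10
  origin_cm <- grid$origin_mm / 10
  media <- do.call(rbind, lapply(grid$media, function(m)
    c(m$mu_a, m$mu_s, m$g)))
  kind <- match(source$kind, c("pencil", "disk", "plane")) - 1L

  raw <- mc_propagate_cpp(
    labels = as.integer(grid$labels), dim = as.integer(d),
    vox_cm = vox_cm, origin_cm = origin_cm, media = media,
    source_kind = kind, src_x = source$x / 10, src_y = source$y / 10,
    theta = source$zenith_deg * pi / 180,
    diameter_cm = source$diameter / 10,
    gaussian_profile = as.integer(source$profile == "gaussian"),
    n_photons = n_photons, seed = seed,
    w_threshold = roulette_threshold, roulette_m = roulette_m)

  voxvol <- prod(vox_cm)
  fluence <- array(raw$track_sum / (voxvol * n_photons), dim = d)
  escape <- matrix(raw$escape_sum / (vox_cm[1] * vox_cm[2] * n_photons),
                   d[1], d[2])
  ledger <- c(
    launched = 1,
    absorbed = raw$absorbed / n_photons,
    escaped = (raw$escaped_top + raw$escaped_other) / n_photons,
    residual = (raw$roulette_killed - raw$roulette_gain) / n_photons)
  structure(
    list(fluence = fluence, escape = escape, ledger = ledger,
         escaped_top = raw$escaped_top / n_photons,
         grid = grid, source = source,
         n_photons = n_photons, seed = seed),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %g photons, seed %s\n",
              x$n_photons, format(x$seed)))
  cat(sprintf("  ledger: absorbed %.4f, escaped %.4f, residual %.2e\n",
              x$ledger["absorbed"], x$ledger["escaped"],
              x$ledger["residual"]))
  invisible(x)
}

# z index of the first non-water voxel in each (x, y) column; NA for
# columns that are water throughout. Sweeping z from the bottom up leaves
# the shallowest non-water index in place.
surface_z_index <- function(grid) {
  d <- dim(grid$labels)
  water <- which(names(grid$media) == "water")
  sz <- matrix(NA_integer_, d[1], d[2])
  for (k in rev(seq_len(d[3]))) {
    m <- grid$labels[, , k] != water
    sz[m] <- k
  }
  sz
}

#' Radial surface fluence profile (the microprobe observable)
#'
#' Emulates an isotropic scalar-irradiance microprobe in contact with the
#' surface: for each requested radius the fluence rate of the topmost
#' non-water voxel layer is averaged over a small collection band around
#' the probe position.
#'
#' Two sampling modes are provided. `"along_wall"` moves the probe along
#' the wall axis (y) at the beam's x position, as in the experiment where
#' the probe tracked the coenosteum/coenosarc crest; both +y and -y
#' positions are averaged. `"annulus"` averages over a full annulus of
#' radius r around the beam center and is intended for homogeneous
#' validation geometries.
#'
#' @param result A [propagate()] result.
#' @param radii Probe distances from the beam center \[mm\], strictly
#'   increasing.
#' @param center Beam center `c(x, y)` \[mm\]; defaults to the source
#'   position.
#' @param mode `"along_wall"` or `"annulus"`.
#' @param band_x,band_y Collection half-widths \[mm\] for `"along_wall"`
#'   (x across the crest, y along the wall).
#' @param band_r Annulus half-width \[mm\] for `"annulus"`.
#' @param depth Collection depth below the surface \[mm\] (the probe's
#'   contact layer).
#' @param observable `"fluence"` (in-contact fluence of the surface voxel
#'   layer, default) or `"escape"` (escaping irradiance through the top
#'   boundary above the probe position).
#' @return A `radial_profile` data.frame with columns `r_mm`, `phi`
#'   (W cm^-2 per W delivered) and `n_voxels`.
#' @export
surface_radial_profile <- function(result, radii, center = NULL,
                                   mode = c("along_wall", "annulus"),
                                   band_x = 1.0, band_y = 0.5,
                                   band_r = 0.5, depth = 0.25,
                                   observable = c("fluence", "escape")) {
  stopifnot(inherits(result, "simulation_result"))
  mode <- match.arg(mode)
  observable <- match.arg(observable)
  grid <- result$grid
  if (is.null(center)) center <- c(result$source$x, result$source$y)
  if (is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing")
  d <- dim(grid$labels)
  vx <- grid$voxel_mm
  xc <- grid$origin_mm[1] + (seq_len(d[1]) - 0.5) * vx[1]
  yc <- grid$origin_mm[2] + (seq_len(d[2]) - 0.5) * vx[2]
  if (max(radii) > max(abs(c(xc, yc))))
    stop("radius outside the voxel domain")
  sz <- surface_z_index(grid)
  ndeep <- max(1L, round(depth / vx[3]))

  collect <- function(ix, iy) {
    # average observable over the surface band of columns (ix, iy)
    vals <- numeric(0)
    for (i in ix) for (j in iy) {
      k <- sz[i, j]
      if (is.na(k)) next
      if (observable == "escape") {
        vals <- c(vals, result$escape[i, j])
      } else {
        kk <- k:min(k + ndeep - 1L, d[3])
        vals <- c(vals, result$fluence[i, j, kk])
      }
    }
    vals
  }

  phi <- numeric(length(radii))
  nvox <- integer(length(radii))
  for (q in seq_along(radii)) {
    r <- radii[q]
    if (mode == "along_wall") {
      ix <- which(abs(xc - center[1]) <= band_x + 1e-9)
      iy <- which(abs(abs(yc - center[2]) - r) <= band_y + 1e-9)
    } else {
      rr <- sqrt(outer((xc - center[1])^2, (yc - center[2])^2, "+"))
      sel <- which(abs(rr - r) <= band_r + 1e-9, arr.ind = TRUE)
      vals <- numeric(0)
      if (nrow(sel)) {
        vals <- unlist(lapply(seq_len(nrow(sel)), function(s) {
          collect(sel[s, 1], sel[s, 2])
        }))
      }
      phi[q] <- mean(vals)
      nvox[q] <- length(vals)
      next
    }
    vals <- collect(ix, iy)
    phi[q] <- mean(vals)
    nvox[q] <- length(vals)
  }
  structure(data.frame(r_mm = radii, phi = phi, n_voxels = nvox),
            class = c("radial_profile", "data.frame"))
}

#' Axial (depth) fluence profile through one column
#'
#' Returns the fluence rate versus depth z through the column at `(x, y)`,
#' optionally averaged over a band of neighboring columns to suppress
#' Monte Carlo noise.
#'
#' @param result A [propagate()] result.
#' @param x,y Column position \[mm\].
#' @param band_x,band_y Averaging half-widths \[mm\].
#' @return A data.frame with columns `z_mm` and `phi` (W cm^-2 per W
#'   delivered).
#' @export
axial_profile <- function(result, x = 0, y = 0, band_x = 0, band_y = 0) {
  stopifnot(inherits(result, "simulation_result"))
  grid <- result$grid
  d <- dim(grid$labels)
  vx <- grid$voxel_mm
  xc <- grid$origin_mm[1] + (seq_len(d[1]) - 0.5) * vx[1]
  yc <- grid$origin_mm[2] + (seq_len(d[2]) - 0.5) * vx[2]
  ix <- which(abs(xc - x) <= band_x + vx[1] / 2 + 1e-9)
  iy <- which(abs(yc - y) <= band_y + vx[2] / 2 + 1e-9)
  if (!length(ix) || !length(iy)) stop("column outside the voxel domain")
  phi <- apply(result$fluence[ix, iy, , drop = FALSE], 3, mean)
  data.frame(z_mm = (seq_len(d[3]) - 0.5) * vx[3], phi = phi)
}

#' Write a radial or axial profile to CSV
#'
#' @param profile A data.frame from [surface_radial_profile()] or
#'   [axial_profile()].
#' @param path Output CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write a fluence volume as a multi-page TIFF stack
#'
#' One 32-bit float page per z slice, normalized to the volume maximum
#' (TIFF stores \[0, 1\]); the scale factor and grid metadata go to a JSON
#' sidecar `<path>.meta.json`. Requires the `tiff` package.
#'
#' @param result A [propagate()] result.
#' @param path Output TIFF path.
#' @export
write_fluence_tiff <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF volumes requires the 'tiff' package")
  f <- result$fluence
  mx <- max(f)
  pages <- lapply(seq_len(dim(f)[3]), function(k)
    t(f[, , k]) / ifelse(mx > 0, mx, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale_max = mx, units = "W cm^-2 per W delivered",
         voxel_mm = result$grid$voxel_mm,
         origin_mm = result$grid$origin_mm,
         n_photons = result$n_photons, seed = result$seed),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
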