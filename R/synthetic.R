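#' Configuration for a synthetic microprobe measurement series
#'
#' Describes everything needed to emulate the radial scalar-irradiance
#' measurement: the geometry stage (intact coral or bare skeleton), the
#' true optical properties, the 636 nm collimated laser beam on the wall
#' crest, the probe radii, an unknown instrument calibration constant, and
#' multiplicative lognormal replicate noise.
#'
#' @param stage `"skeleton"` (bare skeleton) or `"coral"` (two-layer).
#' @param tissue_truth,skeleton_truth True [make_medium()] properties used
#'   by the forward simulation (`tissue_truth` ignored for the skeleton
#'   stage).
#' @param radii Probe radii \[mm\]; must include the 2 mm reference.
#' @param K_true True calibration constant \[counts cm^-2\] mapping fluence
#'   to signal; arbitrary by construction (the fit is invariant to it).
#' @param cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise (>= 0). The default 0.05 stands in for the laser's
#'   ~2% power stability plus probe positioning error.
#' @param n_replicates Replicates per radius (>= 1).
#' @param n_photons Photons for the generating forward run.
#' @param seed Seed for both the kernel and the replicate noise.
#' @param params Geometry parameters.
#' @param source Laser source specification.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(stage = c("skeleton", "coral"),
                             tissue_truth = make_medium(1.8, 10),
                             skeleton_truth = make_medium(0.01, 3.4),
                             radii = c(2, 5, 8, 11, 14, 17, 20),
                             K_true = 1e4, cv = 0.05,
                             n_replicates = 15, n_photons = 1.5e5,
                             seed = 1,
                             params = coral_model_params(),
                             source = source_spec("disk")) {
  stage <- match.arg(stage)
  if (cv < 0) stop("cv must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!any(abs(radii - 2) < 1e-9))
    stop("radii must include the 2 mm reference")
  structure(list(stage = stage, tissue_truth = tissue_truth,
                 skeleton_truth = skeleton_truth, radii = radii,
                 K_true = K_true, cv = cv, n_replicates = n_replicates,
                 n_photons = n_photons, seed = seed, params = params,
                 source = source),
            class = "synthetic_config")
}

#' Default synthetic configurations for the two inverse stages
#'
#' The skeleton stage uses the bare-skeleton geometry with the recovered
#' skeletal properties (mu_a = 0.01, mu_s' = 3.4 cm^-1) as ground truth
#' and 15 replicates; the coral stage uses the two-layer geometry with
#' tissue truth mu_a = 1.8, mu_s' = 10 cm^-1 over the same skeleton and
#' 13 replicates. Both use the 636 nm, 2.05 mm Gaussian beam on the wall
#' crest and seven probe radii from 2 to 20 mm.
#'
#' @param cv Replicate noise CV.
#' @param seed Seed.
#' @param params Geometry parameters shared by both stages.
#' @return A list with elements `skeleton` and `coral`, each a
#'   [synthetic_config()].
#' @export
default_synthetic_configs <- function(cv = 0.05, seed = 1,
                                      params = coral_model_params()) {
  list(
    skeleton = synthetic_config("skeleton", cv = cv, n_replicates = 15,
                                seed = seed, params = params),
    coral = synthetic_config("coral", cv = cv, n_replicates = 13,
                             seed = seed, params = params)
  )
}

#' Generate a synthetic measurement series
#'
#' Runs the forward Monte Carlo simulation at the configured true optical
#' properties, samples the along-wall surface fluence at the probe radii,
#' and emits replicate signals M_i(r) = K_true * phi(r) * eps_i with
#' eps_i lognormal with mean exactly 1 and the configured CV. The ground
#' truth (true properties, noiseless fluence, K_true) is attached as
#' attributes for test harnesses.
#'
#' @param config A [synthetic_config()].
#' @return A `measurement_series` with attributes `truth` (list with the
#'   generating media and `K_true`) and `phi_true` (noiseless fluence at
#'   the radii).
#' @export
generate_measurement <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- if (config$stage == "skeleton") {
    build_bare_skeleton(config$params, skeleton = config$skeleton_truth)
  } else {
    build_coral_model(config$params, tissue = config$tissue_truth,
                      skeleton = config$skeleton_truth)
  }
  res <- propagate(grid, config$source, n_photons = config$n_photons,
                   seed = config$seed)
  phi <- surface_radial_profile(res, config$radii)$phi
  if (any(phi <= 0))
    stop("zero fluence at a probe radius; increase n_photons")

  nrep <- config$n_replicates
  nr <- length(config$radii)
  set.seed(config$seed)
  if (config$cv > 0) {
    sdlog <- sqrt(log(1 + config$cv^2))
    eps <- rlnorm(nr * nrep, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    eps <- rep(1, nr * nrep)
  }
  M <- measurement_series(
    r_mm = rep(config$radii, times = nrep),
    signal_au = config$K_true * rep(phi, times = nrep) * eps,
    replicate = rep(seq_len(nrep), each = nr),
    label = config$stage)
  attr(M, "truth") <- list(
    tissue = config$tissue_truth, skeleton = config$skeleton_truth,
    K_true = config$K_true, stage = config$stage)
  attr(M, "phi_true") <- phi
  M
}
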