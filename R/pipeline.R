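#' Assemble a run configuration
#'
#' Bundles every setting of the end-to-end analysis into one object:
#' per-medium optical properties, geometry, source, fit settings,
#' synthetic-measurement settings and execution settings. Any section can
#' be overridden; the remaining sections keep their defaults. A
#' configuration can also be loaded from a YAML file with
#' [read_run_config()].
#'
#' @param media List with `water`, `tissue`, `skeleton` ([make_medium()]
#'   objects); `tissue`/`skeleton` are the synthetic ground truths.
#' @param geometry A [coral_model_params()].
#' @param source A [source_spec()] for the laser stages.
#' @param fit List of fit settings (`mu_a_fixed`, screen grids, photon
#'   counts, `r_ref`).
#' @param synth List of synthetic-measurement settings (`cv`,
#'   `n_replicates_skeleton`, `n_replicates_coral`, `n_photons`).
#' @param execution List: `seed`, `photons_experiment`, `out_dir` (NULL to
#'   skip writing files), `run_experiments`.
#' @return A `run_config` list.
#' @export
run_config <- function(media = list(water = water_medium(),
                                    tissue = make_medium(1.8, 10),
                                    skeleton = make_medium(0.01, 3.4)),
                       geometry = coral_model_params(),
                       source = source_spec("disk"),
                       fit = list(mu_a_fixed = 0.01,
                                  screen_mu_a = c(0.01, 0.056, 0.316,
                                                  1.78, 10),
                                  screen_mu_s_prime = c(0.1, 0.562, 3.15,
                                                        17.8, 100),
                                  r_ref = 2,
                                  photons_screen = NULL,
                                  photons_fit = NULL),
                       synth = list(cv = 0.05,
                                    n_replicates_skeleton = 15,
                                    n_replicates_coral = 13,
                                    radii = c(2, 5, 8, 11, 14, 17, 20),
                                    n_photons = 1.5e5),
                       execution = list(seed = 1,
                                        photons_experiment = 2e5,
                                        experiment_params = NULL,
                                        out_dir = NULL,
                                        run_experiments = TRUE)) {
  structure(list(media = media, geometry = geometry, source = source,
                 fit = fit, synth = synth, execution = execution),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a nested YAML file with sections `media` (each medium a mapping
#' with `mu_a`, `mu_s_prime`, `g`, `n`), `geometry`, `source`, `fit`,
#' `synth`, `execution`; absent keys keep the package defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  if (!is.null(y$media)) {
    for (nm in names(y$media))
      cfg$media[[nm]] <- do.call(make_medium, y$media[[nm]])
  }
  if (!is.null(y$geometry))
    cfg$geometry <- do.call(coral_model_params, y$geometry)
  if (!is.null(y$source))
    cfg$source <- do.call(source_spec, y$source)
  for (sec in c("fit", "synth", "execution")) {
    if (!is.null(y[[sec]]))
      for (nm in names(y[[sec]])) cfg[[sec]][[nm]] <- y[[sec]][[nm]]
  }
  cfg
}

config_hash <- function(config) {
  # strip function environments so the hash depends only on values
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(
    rapply(unclass(config), function(x)
      if (is.numeric(x) || is.character(x) || is.logical(x)) x else NULL,
      how = "unlist"),
    f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full two-stage analysis end to end
#'
#' Executes, in order: (1) synthetic (or supplied) bare-skeleton
#' measurement, (2) skeleton-stage fit of mu_s' with mu_a fixed, (3)
#' synthetic (or supplied) intact-coral measurement, (4) tissue-stage fit
#' of (mu_a, mu_s') over the fitted skeleton, and (5, optional) the
#' vertical- and oblique-sun illumination experiments using the fitted
#' properties. A manifest records the configuration hash, seeds and stage
#' energy ledgers so every output is traceable.
#'
#' @param config A [run_config()].
#' @param M_skeleton,M_coral Optional real `measurement_series` to use in
#'   place of the synthetic ones (same CSV schema either way).
#' @return An `analysis_bundle` list: `skeleton_fit`, `tissue_fit`,
#'   `experiments` (or NULL), `measurements`, `manifest`.
#' @export
run_full_analysis <- function(config = run_config(),
                              M_skeleton = NULL, M_coral = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$execution$seed
  radii <- config$synth$radii
  out_dir <- config$execution$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  say <- function(fmt, ...) message(sprintf(fmt, ...))

  fit_extra <- function() {
    out <- list()
    if (!is.null(config$fit$photons_screen))
      out$photons_screen <- config$fit$photons_screen
    if (!is.null(config$fit$photons_fit))
      out$photons_fit <- config$fit$photons_fit
    out
  }
  if (is.null(M_skeleton)) {
    M_skeleton <- generate_measurement(synthetic_config(
      "skeleton", skeleton_truth = config$media$skeleton,
      radii = radii, cv = config$synth$cv,
      n_replicates = config$synth$n_replicates_skeleton,
      n_photons = config$synth$n_photons,
      seed = seed, params = config$geometry, source = config$source))
  }
  skel_fit <- do.call(extract_skeleton_properties, c(list(
    M_skeleton, params = config$geometry,
    mu_a_fixed = config$fit$mu_a_fixed,
    screen_mu_s_prime = config$fit$screen_mu_s_prime,
    source = config$source, seed = seed + 1000L), fit_extra()))
  say("skeleton stage: mu_s' = %.3g cm^-1 (SSE %.3g)",
      skel_fit$mu_s_prime, skel_fit$sse)
  skeleton_props <- make_medium(skel_fit$mu_a, skel_fit$mu_s_prime)

  if (is.null(M_coral)) {
    M_coral <- generate_measurement(synthetic_config(
      "coral", tissue_truth = config$media$tissue,
      skeleton_truth = config$media$skeleton,
      radii = radii, cv = config$synth$cv,
      n_replicates = config$synth$n_replicates_coral,
      n_photons = config$synth$n_photons,
      seed = seed + 1L, params = config$geometry, source = config$source))
  }
  tissue_fit <- do.call(extract_tissue_properties, c(list(
    M_coral, skeleton_props, K_fixed = skel_fit$K,
    params = config$geometry,
    screen_mu_a = config$fit$screen_mu_a,
    screen_mu_s_prime = config$fit$screen_mu_s_prime,
    source = config$source, seed = seed + 2000L), fit_extra()))
  say("tissue stage: mu_a = %.3g, mu_s' = %.3g cm^-1 (SSE %.3g)",
      tissue_fit$mu_a, tissue_fit$mu_s_prime, tissue_fit$sse)
  tissue_props <- make_medium(tissue_fit$mu_a, tissue_fit$mu_s_prime)

  experiments <- NULL
  if (isTRUE(config$execution$run_experiments)) {
    np <- config$execution$photons_experiment
    ep <- config$execution$experiment_params
    if (is.null(ep)) ep <- experiment_params()
    ep_oblique <- config$execution$experiment_params
    if (is.null(ep_oblique))
      ep_oblique <- experiment_params(dx = 0.15, dy = 0.15, dz = 0.05)
    experiments <- list(
      vertical = run_vertical_sun(tissue_props, skeleton_props,
                                  params = ep,
                                  n_photons = np, seed = seed + 1L),
      oblique_real = run_oblique_sun(tissue_props, skeleton_props,
                                     params = ep_oblique,
                                     skeleton_mode = "real",
                                     n_photons = np, seed = seed + 2L),
      oblique_replaced = run_oblique_sun(tissue_props, skeleton_props,
                                         params = ep_oblique,
                                         skeleton_mode = "tissue-replaced",
                                         n_photons = np, seed = seed + 2L))
    say("experiments: tissue max %.2fx, water max %.2fx, far wall %.3g vs %.3g",
        experiments$vertical$max_tissue_enh,
        experiments$vertical$max_water_enh,
        experiments$oblique_real$far_wall_enh,
        experiments$oblique_replaced$far_wall_enh)
    for (e in experiments) {
      if (abs(sum(e$ledger[-1]) - 1) > 1e-6)
        warning("energy ledger violation in ", e$scenario)
    }
  }

  manifest <- list(
    config_hash = config_hash(config), seed = seed,
    skeleton = list(mu_a = skel_fit$mu_a,
                    mu_s_prime = skel_fit$mu_s_prime,
                    K = skel_fit$K, sse = skel_fit$sse),
    tissue = list(mu_a = tissue_fit$mu_a,
                  mu_s_prime = tissue_fit$mu_s_prime,
                  K = tissue_fit$K, sse = tissue_fit$sse),
    package_version = as.character(utils::packageVersion("coraloptics")))

  if (!is.null(out_dir)) {
    write_measurement_csv(M_skeleton,
                          file.path(out_dir, "measurement_skeleton.csv"))
    write_measurement_csv(M_coral,
                          file.path(out_dir, "measurement_coral.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(skeleton_fit = skel_fit, tissue_fit = tissue_fit,
                 experiments = experiments,
                 measurements = list(skeleton = M_skeleton,
                                     coral = M_coral),
                 manifest = manifest),
            class = "analysis_bundle")
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("<analysis_bundle>\n")
  cat(sprintf("  skeleton: mu_s' = %.3g cm^-1\n",
              x$skeleton_fit$mu_s_prime))
  cat(sprintf("  tissue:   mu_a = %.3g, mu_s' = %.3g cm^-1\n",
              x$tissue_fit$mu_a, x$tissue_fit$mu_s_prime))
  if (!is.null(x$experiments))
    cat(sprintf("  vertical sun: tissue max %.2fx at %.0f um, water max %.2fx\n",
                x$experiments$vertical$max_tissue_enh,
                x$experiments$vertical$depth_of_max_um,
                x$experiments$vertical$max_water_enh))
  cat(sprintf("  config hash %s, seed %s\n",
              x$manifest$config_hash, format(x$manifest$seed)))
  invisible(x)
}
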