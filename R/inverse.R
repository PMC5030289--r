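#' Construct a radial measurement series
#'
#' The experimental observable: microprobe signal M(r) in arbitrary units
#' at a set of radial distances from the beam, with replicate readings per
#' radius.
#'
#' @param r_mm Radial distances \[mm\].
#' @param signal_au Signal values \[a.u.\], > 0, same length as `r_mm`.
#' @param replicate Replicate identifiers (recycled).
#' @param label `"skeleton"` or `"coral"` (free text allowed).
#' @return A `measurement_series` data.frame with columns `r_mm`,
#'   `signal_au`, `replicate`.
#' @export
measurement_series <- function(r_mm, signal_au, replicate = 1L,
                               label = "measurement") {
  stopifnot(length(r_mm) == length(signal_au))
  if (any(!is.finite(signal_au)) || any(signal_au <= 0))
    stop("all signals must be finite and > 0")
  out <- data.frame(r_mm = r_mm, signal_au = signal_au,
                    replicate = rep_len(replicate, length(r_mm)))
  attr(out, "label") <- label
  class(out) <- c("measurement_series", "data.frame")
  out
}

#' Read / write a measurement series as CSV
#'
#' CSV schema: columns `r_mm`, `signal_au`, `replicate`.
#'
#' @param path File path.
#' @param label Series label on read.
#' @export
read_measurement_csv <- function(path, label = "measurement") {
  d <- read.csv(path)
  measurement_series(d$r_mm, d$signal_au, d$replicate, label = label)
}

#' @param M A `measurement_series`.
#' @param truth_sidecar If `TRUE` and `M` carries a synthetic ground-truth
#'   attribute, a JSON sidecar `<path>.truth.json` records the generating
#'   properties alongside the CSV.
#' @rdname read_measurement_csv
#' @export
write_measurement_csv <- function(M, path, truth_sidecar = FALSE) {
  write.csv(as.data.frame(M), path, row.names = FALSE)
  truth <- attr(M, "truth")
  if (isTRUE(truth_sidecar) && !is.null(truth)) {
    jsonlite::write_json(
      list(stage = truth$stage, K_true = truth$K_true,
           tissue = unclass(truth$tissue),
           skeleton = unclass(truth$skeleton),
           phi_true = attr(M, "phi_true")),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# replicate-averaged signal per radius (unweighted; per-radius SD kept for
# reporting only)
average_measurement <- function(M) {
  r <- sort(unique(M$r_mm))
  m <- vapply(r, function(ri) mean(M$signal_au[M$r_mm == ri]), 0)
  s <- vapply(r, function(ri) {
    v <- M$signal_au[M$r_mm == ri]
    if (length(v) > 1) sd(v) else NA_real_
  }, 0)
  data.frame(r_mm = r, signal_au = m, sd = s)
}

# value at the reference radius, log-linearly interpolated between
# neighbors when r_ref is not a sample point (smooth positive decay)
value_at_reference <- function(r, v, r_ref) {
  if (r_ref < min(r) || r_ref > max(r))
    stop("reference radius outside the measured range")
  hit <- which(abs(r - r_ref) < 1e-9)
  if (length(hit)) return(v[hit[1]])
  exp(approx(r, log(v), xout = r_ref)$y)
}

#' Normalize a profile or measurement at a reference radius
#'
#' Divides the series by its value at `r_ref` (replicate-averaged for
#' measurements), so the output equals 1 at the reference radius. This
#' makes arbitrary-unit measurements comparable with absolute-unit
#' simulations. Idempotent and invariant to positive rescaling of the
#' input. If `r_ref` falls between sample points the reference value is
#' interpolated log-linearly.
#'
#' @param x A `radial_profile` or `measurement_series`.
#' @param r_ref Reference radius \[mm\] (default 2 mm).
#' @return The same type, normalized.
#' @export
normalize_at_reference <- function(x, r_ref = 2) {
  if (inherits(x, "measurement_series")) {
    avg <- average_measurement(x)
    ref <- value_at_reference(avg$r_mm, avg$signal_au, r_ref)
    x$signal_au <- x$signal_au / ref
    return(x)
  }
  stopifnot(is.data.frame(x), all(c("r_mm", "phi") %in% names(x)))
  ref <- value_at_reference(x$r_mm, x$phi, r_ref)
  x$phi <- x$phi / ref
  x
}

#' Forward-model profile provider for the bare skeleton
#'
#' Returns a function `(mu_a, mu_s_prime) -> phi(radii)` that builds the
#' candidate skeleton medium, runs the Monte Carlo forward model on a
#' prebuilt bare-skeleton grid with a fixed kernel seed (common random
#' numbers across candidates, so the fit objective is a deterministic,
#' comparatively smooth function of the parameters) and samples the
#' along-wall surface profile.
#'
#' @param params A [coral_model_params()].
#' @param radii Probe radii \[mm\].
#' @param source A [source_spec()]; default is the 2.05 mm Gaussian laser
#'   beam on the wall crest.
#' @param g,n Anisotropy and refractive index for candidate media.
#' @param n_photons Photons per forward evaluation.
#' @param seed Kernel seed shared by all evaluations.
#' @param observable Passed to [surface_radial_profile()].
#' @return A function of `(mu_a, mu_s_prime)` returning the fluence vector.
#' @export
skeleton_forward_provider <- function(params = coral_model_params(),
                                      radii = c(2, 5, 8, 11, 14, 17, 20),
                                      source = source_spec("disk"),
                                      g = 0.9, n = 1.38,
                                      n_photons = 5e4, seed = 1,
                                      observable = "fluence") {
  grid <- build_bare_skeleton(params)
  function(mu_a, mu_s_prime) {
    grid$media$skeleton <- make_medium(mu_a, mu_s_prime, g = g, n = n)
    res <- propagate(grid, source, n_photons = n_photons, seed = seed)
    surface_radial_profile(res, radii, observable = observable)$phi
  }
}

#' Forward-model profile provider for the two-layer coral
#'
#' As [skeleton_forward_provider()], but the candidate properties are the
#' tissue's; the skeleton keeps the fixed properties recovered in the
#' skeleton stage.
#'
#' @inheritParams skeleton_forward_provider
#' @param skeleton_props Fixed skeleton [make_medium()] (from the skeleton
#'   stage).
#' @return A function of `(mu_a, mu_s_prime)` for the tissue.
#' @export
coral_forward_provider <- function(skeleton_props,
                                   params = coral_model_params(),
                                   radii = c(2, 5, 8, 11, 14, 17, 20),
                                   source = source_spec("disk"),
                                   g = 0.9, n = 1.38,
                                   n_photons = 5e4, seed = 1,
                                   observable = "fluence") {
  grid <- build_coral_model(params, skeleton = skeleton_props)
  function(mu_a, mu_s_prime) {
    grid$media$tissue <- make_medium(mu_a, mu_s_prime, g = g, n = n)
    res <- propagate(grid, source, n_photons = n_photons, seed = seed)
    surface_radial_profile(res, radii, observable = observable)$phi
  }
}

#' Build a lookup table of simulated radial profiles
#'
#' Runs the forward model over a grid of candidate (mu_a, mu_s') values
#' with common random numbers (the provider's fixed seed), producing the
#' coarse screen used to initialize the simplex refinement. A failed grid
#' point is recorded as a hole (NA profile) and flagged; the table remains
#' usable.
#'
#' @param forward A profile provider (see [skeleton_forward_provider()]).
#' @param mu_a_list,mu_s_prime_list Candidate coefficient grids \[cm^-1\].
#' @param radii Probe radii \[mm\] (metadata; must match the provider).
#' @return A `lookup_table`: entries array of dimension
#'   `(length(mu_a_list), length(mu_s_prime_list), length(radii))`, plus
#'   the axes and a logical `holes` matrix.
#' @export
build_lookup_table <- function(forward, mu_a_list, mu_s_prime_list,
                               radii = c(2, 5, 8, 11, 14, 17, 20)) {
  stopifnot(length(mu_a_list) >= 1, length(mu_s_prime_list) >= 1)
  na <- length(mu_a_list); ns <- length(mu_s_prime_list)
  entries <- array(NA_real_, dim = c(na, ns, length(radii)))
  holes <- matrix(FALSE, na, ns)
  for (i in seq_len(na)) for (j in seq_len(ns)) {
    phi <- tryCatch(forward(mu_a_list[i], mu_s_prime_list[j]),
                    error = function(e) NULL)
    if (is.null(phi)) holes[i, j] <- TRUE else entries[i, j, ] <- phi
  }
  structure(list(mu_a = mu_a_list, mu_s_prime = mu_s_prime_list,
                 radii = radii, entries = entries, holes = holes),
            class = "lookup_table")
}

# profiled linear least-squares scale: K* = sum(M*phi) / sum(phi^2),
# the exact minimizer of sum((M - K*phi)^2) over K
profile_K <- function(M, phi) sum(M * phi) / sum(phi^2)

resolve_weights <- function(weights, m) {
  if (is.null(weights)) return(rep(1, length(m)) / length(m))
  if (identical(weights, "mc_info")) return(m / sum(m))
  stopifnot(is.numeric(weights), length(weights) == length(m),
            all(weights >= 0), any(weights > 0))
  weights / sum(weights)
}

# Weighted residual between a measurement and a candidate profile.
# Non-positive model fluences (track-starved radii) are clamped to a small
# positive floor so every candidate is scored on the same number of
# residual terms; the clamped radii then carry a large, finite misfit.
measurement_sse <- function(m, phi, w, log_space = FALSE, K_fixed = NULL) {
  floor_phi <- 1e-6 * max(phi, 1e-300)
  phi <- pmax(phi, floor_phi)
  if (log_space) {
    lk <- if (is.null(K_fixed)) {
      sum(w * (log(m) - log(phi)))  # weighted-LS profile of log K
    } else log(K_fixed)
    sum(w * (log(m) - lk - log(phi))^2)
  } else {
    k <- if (is.null(K_fixed)) profile_K(m, phi) else K_fixed
    sum(w * (m - k * phi)^2 * length(m))
  }
}

#' Fit a measurement with the forward model: M(r) = K * phi(r)
#'
#' Minimizes the sum of squared residuals between the replicate-averaged
#' measurement M(r) and the scaled model prediction K * phi(r) over the
#' free optical parameters, using Nelder-Mead simplex search on
#' log-transformed parameters (unconstrained search on positive
#' quantities). The calibration constant K is profiled out analytically at
#' each evaluation (its exact linear least-squares solution), so the
#' simplex only searches the shape parameters; K affects the magnitude of
#' the fit, never the shape.
#'
#' @param M A `measurement_series`.
#' @param forward Profile provider `(mu_a, mu_s_prime) -> phi(radii)`
#'   returning the model fluence at the measurement radii.
#' @param free Character vector naming the free parameters, a subset of
#'   `c("mu_a", "mu_s_prime")`.
#' @param init Named numeric starting values for the free parameters.
#' @param fixed Named values for the parameters held fixed.
#' @param r_ref Reference radius \[mm\] used for the calibration constant.
#' @param log_space If `TRUE`, residuals are computed on log signals
#'   instead of linear signals. Off by default (the skeleton-stage fit is
#'   stated on linear values, which weights the near-beam radii most);
#'   the tissue stage turns it on so that both the slope and the absolute
#'   level of the two-decade decay constrain the two free parameters.
#' @param lower,upper Named box bounds for the free parameters (natural
#'   scale). Candidates outside the box are rejected with a distance
#'   penalty, keeping the recovered coefficients within the searched
#'   range.
#' @param K_fixed If supplied, the calibration constant is held at this
#'   value instead of being profiled: the fit then matches calibrated
#'   absolute values, not shape only. Used by the tissue stage, which
#'   inherits the instrument constant determined in the skeleton stage.
#' @param weights Per-radius residual weights. `NULL` (default) weights
#'   all radii equally; `"mc_info"` weights each radius by its
#'   replicate-averaged signal, the Monte Carlo track-information
#'   weighting appropriate for log residuals of track-length tallies
#'   (far, track-starved radii carry proportionally less information).
#' @param control Passed to [stats::optim()] (`reltol` 1e-3, `maxit` 200 by
#'   default).
#' @return A `fit_result`: recovered `mu_a`, `mu_s_prime`, `K` (signal
#'   counts per unit fluence, M = K*phi), `calib` (= 1/K, maps signal to
#'   fluence: phi = calib * M), `sse`, `iterations`, `converged`, the
#'   fixed-parameter record and the fitted profile.
#' @export
fit_measurement <- function(M, forward,
                            free = c("mu_a", "mu_s_prime"),
                            init, fixed = list(), r_ref = 2,
                            log_space = FALSE,
                            lower = NULL, upper = NULL,
                            K_fixed = NULL, weights = NULL,
                            control = list(reltol = 1e-3, maxit = 200)) {
  stopifnot(inherits(M, "measurement_series"))
  free <- match.arg(free, c("mu_a", "mu_s_prime"), several.ok = TRUE)
  if (!all(free %in% names(init)))
    stop("init must name every free parameter")
  avg <- average_measurement(M)
  m <- avg$signal_au
  M_ref <- value_at_reference(avg$r_mm, m, r_ref)
  w <- resolve_weights(weights, m)

  assemble <- function(p) {
    full <- as.list(p)
    for (nm in names(fixed)) full[[nm]] <- fixed[[nm]]
    full
  }
  outside_box <- function(p) {
    d <- 0
    for (nm in names(p)) {
      if (!is.null(lower[[nm]]) && p[[nm]] < lower[[nm]])
        d <- d + (log(lower[[nm]]) - log(p[[nm]]))
      if (!is.null(upper[[nm]]) && p[[nm]] > upper[[nm]])
        d <- d + (log(p[[nm]]) - log(upper[[nm]]))
    }
    d
  }
  objective <- function(logp) {
    p <- setNames(exp(logp), free)
    d_out <- outside_box(p)
    if (d_out > 0) return(1e20 * (1 + d_out))
    full <- assemble(p)
    phi <- forward(full$mu_a, full$mu_s_prime)
    if (any(!is.finite(phi)) || all(phi <= 0)) return(1e30)
    measurement_sse(m, phi, w, log_space = log_space, K_fixed = K_fixed)
  }

  par0 <- log(unlist(init[free]))
  opt <- suppressWarnings(
    optim(par0, objective, method = "Nelder-Mead", control = control))
  best <- setNames(exp(opt$par), free)
  full <- assemble(best)
  phi <- forward(full$mu_a, full$mu_s_prime)
  K <- if (is.null(K_fixed)) profile_K(m, phi) else K_fixed

  structure(
    list(mu_a = full$mu_a, mu_s_prime = full$mu_s_prime,
         K = K, calib = 1 / K, M_ref = M_ref, r_ref = r_ref,
         sse = opt$value, iterations = opt$counts[["function"]],
         converged = opt$convergence == 0,
         free = free, fixed = fixed,
         radii = avg$r_mm, measured = m, predicted = K * phi,
         phi_model = phi),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> mu_a = %.4g cm^-1%s, mu_s' = %.4g cm^-1%s\n",
    x$mu_a, if ("mu_a" %in% names(x$fixed)) " (fixed)" else "",
    x$mu_s_prime, if ("mu_s_prime" %in% names(x$fixed)) " (fixed)" else ""))
  cat(sprintf("  K = %.4g, SSE = %.4g, %d evaluations, converged: %s\n",
              x$K, x$sse, x$iterations, x$converged))
  invisible(x)
}

#' Extract skeleton optical properties from a bare-skeleton measurement
#'
#' Stage one of the inverse pipeline. Skeletal absorption is too weak to
#' influence the lateral attenuation, so mu_a is held fixed (default 0.01
#' cm^-1, the known order of magnitude for coral skeleton at red
#' wavelengths) and only the reduced scattering coefficient is fitted
#' (plus the calibration constant, profiled analytically). A coarse
#' lookup-table screen over `screen_mu_s_prime` chooses the simplex
#' starting point; Nelder-Mead then refines with on-the-fly forward
#' simulations at the provider's fixed seed.
#'
#' @param M Bare-skeleton `measurement_series`.
#' @param params Geometry parameters.
#' @param mu_a_fixed Fixed skeletal absorption coefficient \[cm^-1\].
#' @param screen_mu_s_prime Coarse screen values \[cm^-1\].
#' @param source Laser source.
#' @param g,n Anisotropy and refractive index.
#' @param photons_screen,photons_fit Photons per forward evaluation in the
#'   screen and in the refinement.
#' @param photons_K Photons for one final forward run at the fitted
#'   parameters, used to re-estimate the calibration constant K with low
#'   Monte Carlo noise (the tissue stage inherits this constant, so its
#'   accuracy matters more than that of any single fit evaluation).
#' @param seed Kernel seed (common random numbers).
#' @param control Optimizer control.
#' @return A `fit_result` with an added `screen` data.frame (screened
#'   mu_s' values and their SSE).
#' @export
extract_skeleton_properties <- function(M,
                                        params = coral_model_params(),
                                        mu_a_fixed = 0.01,
                                        screen_mu_s_prime =
                                          c(0.1, 0.562, 3.15, 17.8, 100),
                                        source = source_spec("disk"),
                                        g = 0.9, n = 1.38,
                                        photons_screen = 2e4,
                                        photons_fit = 3e4,
                                        photons_K = 1.2e5,
                                        seed = 1,
                                        control = list(reltol = 1e-3,
                                                       maxit = 40)) {
  avg <- average_measurement(M)
  radii <- avg$r_mm
  fw_screen <- skeleton_forward_provider(
    params, radii, source, g, n, n_photons = photons_screen, seed = seed)
  tab <- build_lookup_table(fw_screen, mu_a_fixed, screen_mu_s_prime, radii)
  w <- resolve_weights(NULL, avg$signal_au)
  sse <- vapply(seq_along(screen_mu_s_prime), function(j) {
    phi <- tab$entries[1, j, ]
    if (any(!is.finite(phi))) return(Inf)
    measurement_sse(avg$signal_au, phi, w)
  }, 0)
  init <- screen_mu_s_prime[which.min(sse)]

  fw_fit <- skeleton_forward_provider(
    params, radii, source, g, n, n_photons = photons_fit, seed = seed)
  fit <- fit_measurement(M, fw_fit, free = "mu_s_prime",
                         init = list(mu_s_prime = init),
                         fixed = list(mu_a = mu_a_fixed),
                         lower = list(mu_s_prime = min(screen_mu_s_prime)),
                         upper = list(mu_s_prime = max(screen_mu_s_prime)),
                         control = control)
  # low-noise re-estimate of the instrument calibration at the optimum
  fw_K <- skeleton_forward_provider(
    params, radii, source, g, n, n_photons = photons_K, seed = seed + 7L)
  phi_K <- fw_K(mu_a_fixed, fit$mu_s_prime)
  fit$K <- profile_K(avg$signal_au, phi_K)
  fit$calib <- 1 / fit$K
  fit$phi_model <- phi_K
  fit$predicted <- fit$K * phi_K

  fit$screen <- data.frame(mu_s_prime = screen_mu_s_prime, sse = sse)
  fit$lookup <- tab
  fit
}

#' Extract tissue optical properties from an intact-coral measurement
#'
#' Stage two of the inverse pipeline. The skeleton keeps the properties
#' recovered in stage one; the tissue layer is added on top and its
#' (mu_a, mu_s') are fitted jointly. A 5 x 5 lookup-table screen over
#' log-spaced candidate grids chooses the simplex start; Nelder-Mead then
#' refines both parameters with on-the-fly forward simulations. The match
#' uses both the slope and the absolute values of the phi(r) curves, not
#' shape only: residuals are taken on log signals (the decay spans about
#' two decades, and log residuals let every probe radius constrain the two
#' free parameters instead of only the near-beam points), weighted by each
#' radius's Monte Carlo track information, calibrated by the skeleton
#' stage's instrument constant when supplied, and bounded by the screened
#' grids.
#'
#' @param M Intact-coral `measurement_series`.
#' @param skeleton_props Fixed skeleton [make_medium()] from stage one.
#' @param K_fixed Instrument calibration constant inherited from the
#'   skeleton stage (`fit_result$K`). When supplied (recommended, and what
#'   [run_full_analysis()] does), the tissue match is on calibrated
#'   absolute values — the scale is anchored by the skeleton-stage
#'   calibration, which resolves the anti-correlated (mu_a, mu_s')
#'   trade-off that a floating scale leaves open. `NULL` profiles K
#'   instead.
#' @param screen_mu_a,screen_mu_s_prime Candidate screen grids \[cm^-1\].
#' @inheritParams extract_skeleton_properties
#' @return A `fit_result` with an added `screen` data.frame over the grid.
#' @export
extract_tissue_properties <- function(M, skeleton_props,
                                      K_fixed = NULL,
                                      params = coral_model_params(),
                                      screen_mu_a =
                                        c(0.01, 0.056, 0.316, 1.78, 10),
                                      screen_mu_s_prime =
                                        c(0.1, 0.562, 3.15, 17.8, 100),
                                      source = source_spec("disk"),
                                      g = 0.9, n = 1.38,
                                      photons_screen = 1e4,
                                      photons_fit = 2.5e4,
                                      seed = 1,
                                      control = list(reltol = 1e-3,
                                                     maxit = 55)) {
  avg <- average_measurement(M)
  radii <- avg$r_mm
  fw_screen <- coral_forward_provider(
    skeleton_props, params, radii, source, g, n,
    n_photons = photons_screen, seed = seed)
  tab <- build_lookup_table(fw_screen, screen_mu_a, screen_mu_s_prime,
                            radii)
  w <- resolve_weights("mc_info", avg$signal_au)
  sse <- matrix(Inf, length(screen_mu_a), length(screen_mu_s_prime))
  for (i in seq_along(screen_mu_a)) for (j in seq_along(screen_mu_s_prime)) {
    phi <- tab$entries[i, j, ]
    if (any(!is.finite(phi))) next
    # same metric as the refinement below
    sse[i, j] <- measurement_sse(avg$signal_au, phi, w,
                                 log_space = TRUE, K_fixed = K_fixed)
  }
  best <- arrayInd(which.min(sse), dim(sse))

  # second-pass mini-screen at half-decade steps around the coarse best:
  # the coarse grids step by factors of ~5.6, too wide for the simplex to
  # reliably cross into the right basin from a grid vertex
  half <- 10^0.375
  mua0 <- screen_mu_a[best[1]]; mus0 <- screen_mu_s_prime[best[2]]
  mua_ref <- pmin(pmax(mua0 * c(1 / half, 1, half), min(screen_mu_a)),
                  max(screen_mu_a))
  mus_ref <- pmin(pmax(mus0 * c(1 / half, 1, half), min(screen_mu_s_prime)),
                  max(screen_mu_s_prime))
  sse_ref <- matrix(Inf, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    phi <- tryCatch(fw_screen(mua_ref[i], mus_ref[j]), error = function(e) NULL)
    if (is.null(phi)) next
    sse_ref[i, j] <- measurement_sse(avg$signal_au, phi, w,
                                     log_space = TRUE, K_fixed = K_fixed)
  }
  best_ref <- arrayInd(which.min(sse_ref), dim(sse_ref))
  init_mu_a <- mua_ref[best_ref[1]]
  init_mu_s <- mus_ref[best_ref[2]]

  fw_fit <- coral_forward_provider(
    skeleton_props, params, radii, source, g, n,
    n_photons = photons_fit, seed = seed)
  fit <- fit_measurement(
    M, fw_fit, free = c("mu_a", "mu_s_prime"),
    init = list(mu_a = init_mu_a, mu_s_prime = init_mu_s),
    log_space = TRUE, K_fixed = K_fixed, weights = "mc_info",
    lower = list(mu_a = min(screen_mu_a),
                 mu_s_prime = min(screen_mu_s_prime)),
    upper = list(mu_a = max(screen_mu_a),
                 mu_s_prime = max(screen_mu_s_prime)),
    control = control)
  fit$screen <- data.frame(
    mu_a = rep(screen_mu_a, times = length(screen_mu_s_prime)),
    mu_s_prime = rep(screen_mu_s_prime, each = length(screen_mu_a)),
    sse = as.vector(sse))
  fit$lookup <- tab
  fit
}

#' Write a fit report as JSON
#'
#' Records the fitted and fixed coefficients, calibration, residual,
#' convergence diagnostics and the fitted profile.
#'
#' @param fit A `fit_result`.
#' @param path Output JSON path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(mu_a = fit$mu_a, mu_s_prime = fit$mu_s_prime,
         K = fit$K, calib = fit$calib,
         free = fit$free, fixed = fit$fixed,
         sse = fit$sse, iterations = fit$iterations,
         converged = fit$converged, r_ref = fit$r_ref,
         radii_mm = fit$radii, measured = fit$measured,
         predicted = fit$predicted),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Calibrate a measurement into absolute fluence units
#'
#' Applies the calibration constant from a fit, CALIB = 1/K (units of
#' fluence per signal count, derived so that CALIB * M(r) overlays the
#' model phi(r)), to convert an arbitrary-unit measurement into W cm^-2
#' per W delivered.
#'
#' @param M A `measurement_series` containing the fit's reference radius.
#' @param fit A `fit_result`.
#' @return A `radial_profile` data.frame of calibrated values (replicate
#'   averages).
#' @export
calibrate_measurement <- function(M, fit) {
  stopifnot(inherits(fit, "fit_result"))
  avg <- average_measurement(M)
  if (fit$r_ref < min(avg$r_mm) || fit$r_ref > max(avg$r_mm))
    stop("measurement does not contain the fit's reference radius")
  structure(data.frame(r_mm = avg$r_mm, phi = fit$calib * avg$signal_au,
                       n_voxels = NA_integer_),
            class = c("radial_profile", "data.frame"))
}
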