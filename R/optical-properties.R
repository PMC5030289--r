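#' Define an optical medium from its reduced scattering coefficient
#'
#' Constructs an `optical_medium` object holding the inherent optical
#' properties of a participating medium: absorption coefficient \eqn{\mu_a}
#' \[cm\eqn{^{-1}}\], scattering coefficient \eqn{\mu_s} \[cm\eqn{^{-1}}\],
#' scattering anisotropy \eqn{g} (mean cosine of the deflection angle) and
#' refractive index \eqn{n}. The medium is parameterized by the *reduced*
#' scattering coefficient \eqn{\mu_s' = \mu_s (1 - g)}, the quantity that
#' governs diffusive transport and the one recovered by the inverse fit;
#' \eqn{\mu_s} is derived as \eqn{\mu_s'/(1-g)}.
#'
#' @param mu_a Absorption coefficient \[cm^-1\], >= 0.
#' @param mu_s_prime Reduced scattering coefficient \[cm^-1\], >= 0.
#' @param g Scattering anisotropy, strictly inside (-1, 1). Tissue-optics
#'   convention for visible light is `g = 0.9` (strongly forward scattering).
#' @param n Refractive index, >= 1. Transport assumes index-matched
#'   boundaries, so `n` is carried as metadata.
#'
#' @return An object of class `optical_medium`: a list with fields `mu_a`,
#'   `mu_s`, `mu_s_prime`, `g`, `n`.
#'
#' @examples
#' tissue <- make_medium(mu_a = 1.8, mu_s_prime = 10, g = 0.9)
#' tissue$mu_s # 100 cm^-1
#' @export
make_medium <- function(mu_a, mu_s_prime, g = 0.9, n = 1.38) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L,
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L,
            is.numeric(g), length(g) == 1L,
            is.numeric(n), length(n) == 1L)
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s_prime < 0) stop("mu_s_prime must be >= 0")
  if (abs(g) >= 1) stop("anisotropy g must satisfy |g| < 1")
  if (n < 1) stop("refractive index n must be >= 1")
  if (mu_a == 0 && mu_s_prime == 0)
    stop("a participating medium needs mu_a > 0 or mu_s_prime > 0")
  structure(
    list(mu_a = mu_a, mu_s = mu_s_prime / (1 - g),
         mu_s_prime = mu_s_prime, g = g, n = n),
    class = "optical_medium"
  )
}

#' @export
print.optical_medium <- function(x, ...) {
  cat(sprintf(
    "<optical_medium> mu_a = %g cm^-1, mu_s = %g cm^-1 (mu_s' = %g), g = %g, n = %g\n",
    x$mu_a, x$mu_s, x$mu_s_prime, x$g, x$n))
  invisible(x)
}

#' Effective internal reflectance at a refractive-index boundary
#'
#' Empirical internal reflectance for diffuse light at a boundary with
#' relative refractive index `n_rel` (medium over surroundings), using the
#' standard tissue-optics polynomial
#' \deqn{r_i = -1.440 n^{-2} + 0.710 n^{-1} + 0.668 + 0.0636 n}
#' for `n_rel > 1`, and 0 at matched indices. This quantifies the fraction of
#' light attempting to escape the tissue that is internally reflected back.
#' For coral tissue (n = 1.38) under seawater (n = 1.33) the value is about
#' 0.08; for the same tissue in air it rises to about 0.51, which is why
#' underwater measurements are far less affected by boundary mismatch.
#'
#' The transport loop itself assumes matched indices everywhere; this utility
#' exists to quantify the size of that approximation.
#'
#' @param n_rel Relative refractive index (> 0). Values <= 1 return 0.
#' @return Internal reflectance fraction in \[0, 1).
#' @examples
#' internal_reflectance(1.38 / 1.33) # ~0.08
#' internal_reflectance(1.38 / 1.00) # ~0.51
#' @export
internal_reflectance <- function(n_rel) {
  stopifnot(is.numeric(n_rel))
  if (any(n_rel <= 0)) stop("n_rel must be positive")
  ri <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  ri[n_rel <= 1] <- 0
  pmin(pmax(ri, 0), 1 - 1e-12)
}
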