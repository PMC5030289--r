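Package: coraloptics
Title: Monte Carlo Radiative Transfer and Inverse Optics for Coral Tissue and Skeleton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelized Monte Carlo photon transport for a simplified two-layer
    faviid coral model (living tissue draped over a scattering aragonite
    skeleton), together with the inverse procedure that extracts inherent
    optical properties (absorption coefficient and reduced scattering
    coefficient) from radial fluence-attenuation measurements made with
    scalar-irradiance microprobes. Includes a synthetic measurement
    generator emulating the microprobe experiment, lookup-table screening
    plus Nelder-Mead least-squares refinement of M(r) = K*phi(r), and
    forward illumination experiments predicting in-tissue light enhancement
    under vertical and oblique sun.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
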