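# coraloptics

Monte Carlo radiative transfer and inverse optics for coral tissue and
skeleton.

## The problem

Massive faviid corals are outstanding light harvesters: the
*Symbiodinium* algae embedded in their tissue photosynthesize near the
theoretical quantum limit. Part of the mechanism is optical, but the
inherent optical properties of *living* coral tissue — the absorption
coefficient μa [cm⁻¹] and the reduced scattering coefficient
μs′ = μs(1−g) [cm⁻¹] — cannot be measured directly on an intact colony.
They must be inferred by solving an inverse radiative-transfer problem:
find the optical properties whose simulated light field reproduces the
measured lateral attenuation of fluence rate (scalar irradiance) away
from a narrow laser beam on the coral surface.

`coraloptics` implements that analysis end to end, for anyone studying
photon transport in corals or similar layered biological media:

* a voxelized Monte Carlo solver of the radiative transfer equation
  (hop / drop / spin / roulette, Henyey–Greenstein phase function,
  track-length fluence estimator, exact energy ledger), with a compiled
  kernel and per-photon reproducible random streams;
* the simplified two-layer faviid geometry: skeletal walls (coenosteum)
  and corallite cups with a conformal living-tissue drape under water;
* the two-stage inverse procedure: fit the bare-skeleton measurement
  first (μa fixed at 0.01 cm⁻¹, μs′ and the instrument calibration K
  free), then fit the intact-coral measurement for the tissue pair
  (μa, μs′) with the skeleton properties and calibration held fixed —
  lookup-table screening over log-spaced grids plus Nelder–Mead
  refinement of M(r) = K·φ(r) with common random numbers;
* a synthetic microprobe-measurement generator (radial series with
  replicate noise) so the whole pipeline is testable without the
  original laboratory data, which were never deposited;
* forward illumination experiments: vertical and 45° sun on the fitted
  colony, including the skeleton-replaced-by-tissue contrast that
  demonstrates trans-skeletal light transport.

## Worked example

The full two-stage analysis on synthetic data generated at the fitted
faviid properties (skeleton μa = 0.01, μs′ = 3.4 cm⁻¹; tissue μa = 1.8,
μs′ = 10 cm⁻¹):

```r
library(coraloptics)

bundle <- run_full_analysis(run_config(execution = list(
  seed = 1, photons_experiment = 3e5, run_experiments = TRUE,
  experiment_params = NULL, out_dir = NULL)))
bundle
```

```
skeleton stage: mu_s' = 3.82 cm^-1 (SSE 2.53e+04)
tissue stage: mu_a = 1.65, mu_s' = 9.03 cm^-1 (SSE 0.00293)
experiments: tissue max 1.93x, water max 1.53x, far wall 0.231 vs 0.141
<analysis_bundle>
  skeleton: mu_s' = 3.82 cm^-1
  tissue:   mu_a = 1.65, mu_s' = 9.03 cm^-1
  vertical sun: tissue max 1.93x at 363 um, water max 1.53x
  config hash d340fa5071161893360a11cad534fe9b, seed 1
```

Reading the output: the skeleton stage recovered a reduced scattering
coefficient of 3.82 cm⁻¹ from the noisy synthetic bare-skeleton series
(generating truth 3.4 cm⁻¹, i.e. within the Monte Carlo and replicate
noise of a single dataset), and the tissue stage recovered
(μa, μs′) = (1.65, 9.03) cm⁻¹ against a truth of (1.8, 10). With those
fitted properties, vertically incident sun builds the fluence rate up to
about twice the incident irradiance on a broad sub-surface plateau in
the upper tissue (about 1.75× already 50–100 µm down, peaking around
300–400 µm), and the light escaping back out of the tissue raises the
fluence rate in the water just above the colony to about 1.5× the
downwelling irradiance. The far-wall figures quantify trans-skeletal
transport: tissue on the shaded side of a skeletal wall under 45° sun
receives 0.231× the incident irradiance with the real, weakly
attenuating skeleton, versus 0.141× when the skeleton is replaced by a
solid mass of tissue.

Individual stages are available as plain functions
(`build_coral_model()`, `propagate()`, `surface_radial_profile()`,
`generate_measurement()`, `extract_skeleton_properties()`,
`extract_tissue_properties()`, `run_vertical_sun()`, ...); see the
methods vignette (`vignettes/coral-optics-methods.Rmd`) for the model,
its assumptions, and every numerical choice.

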