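# Shared fixtures: small geometries that keep Monte Carlo tests fast while
# still exercising the full voxel machinery.

# homogeneous-slab container: shallow domain, isotropic-friendly voxels
slab_params <- function(dx = 0.25, dz = 0.25, domain = 20, depth = 10) {
  coral_model_params(domain_x = domain, domain_y = domain,
                     domain_z = depth, dx = dx, dy = dx, dz = dz,
                     corallite_depth = 6, tissue_thickness = 1,
                     water_depth = 1e-3)
}

# compact coral geometry for fast label/transport checks
small_coral_params <- function() {
  coral_model_params(domain_x = 26, domain_y = 8, domain_z = 14,
                     dx = 0.25, dy = 0.25, dz = 0.25)
}

# reduced measurement geometry: shorter wall axis, four radii
small_measure_params <- function() {
  coral_model_params(domain_x = 26, domain_y = 30, domain_z = 16,
                     dx = 0.25, dy = 0.25, dz = 0.25)
}
small_radii <- c(2, 5, 8, 11)

laser <- function() source_spec("disk", x = 0, y = 0, diameter = 2.05)
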