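# Shared fixture builders; everything is generated in code at test time.

# Small spherical MR phantom (coarser grid than the acceptance phantom).
small_sphere_spec <- function(radius = 1.5, spacing = 0.1, noise_sd = 0,
                              seed = NULL, intensity = 3) {
  n_xy <- ceiling(2 * radius / spacing) + 24L
  mr_phantom_spec(grid_shape = rep(n_xy, 3), voxel_size = rep(spacing, 3),
                  opening_center = rep(n_xy * spacing / 2, 3),
                  opening_semi_axes = rep(radius, 3),
                  opening_intensity = intensity, background_intensity = 1,
                  reference_box = list(corner = rep(3L, 3), size = rep(8L, 3)),
                  noise_sd = noise_sd, seed = seed)
}

# Amyloid-channel detection wrapper used across plaque tests.
detect_on_field <- function(ph, fixed_threshold = 2, min_size = 20) {
  g <- ph$field$data[, , "amyloid"]
  nrm <- normalize_channel(g, list(corner = c(2, 2), size = c(4, 4)))
  detect_plaques(nrm, fixed_threshold = fixed_threshold, min_size = min_size,
                 pixel_size = ph$field$spacing[1])
}

# Exact double-sum oracle for P(A < B), independent of the MC path.
enumerate_p_less <- function(a, b) {
  mean(outer(a, b, `<`))
}
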