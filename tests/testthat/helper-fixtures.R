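# shared fixtures: built once per test run
the_lib <- build_material_library()
the_model <- stopping_model()

# a small planar microbeam setup reused across engine/transport tests
small_beam <- function(field_mm = 2, type = "planar", E = 100) {
  beam_config("+z", square_field(field_mm), collimator(type),
              mono_spectrum(E), emission_pixel_mm = 0.05)
}

# water phantom with a bone slab spanning z in [z0, z1] mm
slab_phantom <- function(side_mm = 40, voxel_mm = 1, z0 = 15, z1 = 20) {
  n <- round(side_mm / voxel_mm)
  idx <- array(1L, dim = c(n, n, n))
  zc <- (seq_len(n) - 0.5) * voxel_mm
  idx[, , zc > z0 & zc < z1] <- 2L
  dens <- array(1, dim = c(n, n, n))
  dens[idx == 2L] <- 1.85
  voxel_phantom(idx, dens, rep(voxel_mm, 3), c("water", "bone"))
}
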