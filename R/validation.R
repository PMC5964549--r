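# Self-validation: hybrid reconstruction against an independent
# direct-sampling Monte Carlo oracle.

#' Hybrid vs direct-sampling PVDR benchmark
#'
#' Runs the full hybrid chain (photon Monte Carlo on a coarse grid, then
#' 1D kernel convolution on a 5 um lateral grid) in a water cube with a
#' planar microbeam field, and compares the PVDR at the requested depths
#' against an independent direct-sampling oracle: primary interaction
#' sites drawn from the collimator fluence over the finite field,
#' electron energy deposited by straight isotropic CSDA track sampling
#' on the same fine grid.  Both routes share the coarse Monte Carlo
#' primary/scatter doses, so the comparison isolates the electron
#' transport model (analytic kernel convolution vs track sampling).
#'
#' @param n_histories photon histories for the Monte Carlo stage.
#' @param n_oracle primary interaction sites for the oracle.
#' @param seed RNG seed.
#' @param depths_mm depths at which the PVDR is compared.
#' @param side_mm,voxel_mm phantom size and coarse voxel size.
#' @param field_mm lateral field size.
#' @param energy_keV monoenergetic beam energy.
#' @param bin_um fine lateral bin.
#' @return data.frame with `depth_mm`, `pvdr_hybrid`, `pvdr_oracle` and
#'   `rel_diff_percent` (signed, hybrid relative to oracle).
#' @export
hybrid_vs_oracle_pvdr <- function(n_histories = 1e6, n_oracle = 1e6,
                                  seed = 1, depths_mm = c(10, 20),
                                  side_mm = 40, voxel_mm = 1,
                                  field_mm = 2, energy_keV = 100,
                                  bin_um = 5) {
  lib <- build_material_library()
  model <- stopping_model()
  ph <- water_cube(side_mm, voxel_mm)
  col <- collimator("planar", 50, 400)
  beam <- beam_config("+z", square_field(field_mm), col,
                      mono_spectrum(energy_keV),
                      emission_pixel_mm = 0.05)
  dc <- run_transport(ph, beam, n_histories, seed = seed)

  ctr <- side_mm / 2
  margin <- 1  # one voxel beyond the field on each side
  roi <- list(lo = c(ctr - field_mm / 2 - margin, ctr - field_mm / 2,
                     min(depths_mm) - 2),
              hi = c(ctr + field_mm / 2 + margin, ctr + field_mm / 2,
                     max(depths_mm) + 2))
  mg <- reconstruct_field(dc, beam, ph, roi, model, lib, bin_um = bin_um)

  # oracle fine profile shape (depth independent: the lateral site
  # distribution and electron model do not change with depth)
  kern <- polychromatic_kernel(mono_spectrum(energy_keV), lib$water,
                               model, 1)
  dsp <- direct_sampling_profile(col, field_mm, kern, n = n_oracle,
                                 seed = seed + 1, bin_um = bin_um,
                                 margin_um = ceiling(kern$max_sigma * 1e4) +
                                   2 * bin_um)
  # normalise to unit mean over an interior whole number of periods
  nper <- floor((field_mm * 1e3 / col$pitch_um - 1) / 2) * 2
  norm_reg <- abs(dsp$u_um) <= nper / 2 * col$pitch_um
  shape <- dsp$energy / mean(dsp$energy[norm_reg])

  # coarse in-field voxels at each depth supply D_primary/D_scatter
  ax <- 1:2
  infield <- which((seq_len(ph$dims[1]) - 0.5) * voxel_mm > ctr - field_mm / 2 &
                     (seq_len(ph$dims[1]) - 0.5) * voxel_mm < ctr + field_mm / 2)
  rows <- lapply(depths_mm, function(z) {
    prof_h <- extract_profile(mg, z)
    pv_h <- pvdr(prof_h, col)
    iz <- floor(z / voxel_mm) + 1
    dp <- mean(dc$primary[infield, infield, iz])
    ds <- mean(dc$scatter[infield, infield, iz])
    prof_o <- data.frame(position_um = dsp$u_um,
                         dose = ds + dp * shape)
    pv_o <- pvdr(prof_o, col)
    data.frame(depth_mm = z, pvdr_hybrid = pv_h$pvdr,
               pvdr_oracle = pv_o$pvdr,
               rel_diff_percent = 100 * (pv_h$pvdr - pv_o$pvdr) / pv_o$pvdr)
  })
  do.call(rbind, rows)
}
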