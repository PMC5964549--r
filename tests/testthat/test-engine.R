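test_that("modulation function: limits, normalisation, material contrast", {
  nu <- fluence_pattern(collimator("planar"), 5)
  # open field
  k1 <- mono_electron_kernel(20, the_lib$water, the_model, 1)
  expect_identical(modulation_function(k1, fluence_pattern(collimator("open"))), 1)
  # delta-like kernel (sigma << slit width) reproduces the comb
  kd <- mono_electron_kernel(5, the_lib$water, the_model, 1)
  Md <- modulation_function(kd, nu)
  expect_equal(max(Md), 8, tolerance = 0.02)
  expect_lt(min(Md), 1e-6)
  # unit period mean for kernel/pattern combinations
  for (mat in list(the_lib$water, the_lib$bone)) {
    for (E in c(20, 100)) {
      M <- modulation_function(mono_electron_kernel(E, mat, the_model, 1), nu)
      expect_equal(mean(M), 1, tolerance = 1e-9)
    }
  }
  nup <- fluence_pattern(collimator("pencil"), 5)
  M2 <- modulation_function(mono_electron_kernel(30, the_lib$water,
                                                 the_model, 2), nup)
  expect_equal(mean(M2), 1, tolerance = 1e-9)
  # dimensionality mismatch is refused
  expect_error(modulation_function(k1, nup), "dimensionality")
  # denser material -> shorter electron range (sigma ~ 1/rho) ->
  # sharper peaks and deeper valleys for the same electron line
  kw <- mono_electron_kernel(50, the_lib$water, the_model, 1)
  kb <- mono_electron_kernel(50, the_lib$bone, the_model, 1)
  Mw <- modulation_function(kw, nu); Mb <- modulation_function(kb, nu)
  expect_gt(max(Mb), max(Mw))
  expect_lt(min(Mb), min(Mw) + 1e-15)
})

test_that("voxel reconstruction adds the scatter bath to the modulated primary", {
  M <- c(0.5, 1.5, 1, 1)
  expect_equal(reconstruct_voxel(0, 3, M), rep(3, 4))
  expect_equal(reconstruct_voxel(2, 3, rep(1, 4)), rep(5, 4))
  out <- reconstruct_voxel(2, 3, M)
  expect_equal(mean(out), 5, tolerance = 1e-9)
  expect_error(reconstruct_voxel(-1, 0, M))
})

test_that("field reconstruction is periodic, conservative and bounded below by scatter", {
  # commensurate geometry: 0.8 mm voxels = 2 collimator periods
  ph <- water_cube(40, 0.8)
  b <- beam_config("+z", square_field(2.4), collimator("planar"),
                   mono_spectrum(100), 0.05)
  dc <- run_transport(ph, b, 5e4, seed = 8)
  roi <- list(lo = c(16, 16, 4.0), hi = c(24, 24, 24))
  mg <- reconstruct_field(dc, b, ph, roi, bin_um = 5, long_um = 400)
  # voxel-mean energy conservation on interior in-field voxels
  npu <- 160  # fine bins per 0.8 mm voxel
  for (vox_u in 25:26) {
    ku <- vox_u - 20          # voxels 21.. in ROI along u
    dp <- dc$primary[vox_u, 25, 15]
    ds <- dc$scatter[vox_u, 25, 15]
    iu <- ((ku - 1) * npu + 1):(ku * npu)
    seg <- mg$dose[iu, 5, (15 - 5 - 1) * 2 + 1]
    expect_equal(mean(seg), dp + ds, tolerance = 1e-9)
    # electron tails only add: valley dose >= scatter bath
    expect_true(all(seg >= ds - 1e-15 * ds))
  }
  # periodicity: autocorrelation of the central profile peaks at the pitch
  pr <- extract_profile(mg, 12)
  ctr <- abs(pr$position_um) <= 1000
  d <- pr$dose[ctr]
  lags <- 40:120
  ac <- vapply(lags, function(l)
    cor(d[1:(length(d) - l)], d[(1 + l):length(d)]), numeric(1))
  expect_equal(lags[which.max(ac)] * 5, 400)   # 400 um pitch
})

test_that("kernel range contrast appears across a water/bone interface", {
  ph <- slab_phantom(40, 1, 15, 20)
  b <- small_beam()
  dc <- run_transport(ph, b, 1e5, seed = 9)
  roi <- list(lo = c(18, 19, 12), hi = c(22, 21, 19))
  mg <- reconstruct_field(dc, b, ph, roi)
  pr_w <- extract_profile(mg, 14)  # water side
  pr_b <- extract_profile(mg, 17)  # bone side
  # normalised peak shoulder just outside the slit: at 100 keV bone
  # transfers a much larger energy share to long-range photoelectrons
  # (higher photoelectric coefficient), broadening the peak relative
  # to water despite the 1/rho range scaling
  shoulder <- function(p) {
    pk <- max(p$dose)
    mean(p$dose[abs(abs(p$position_um) - 37.5) < 5]) / pk
  }
  expect_gt(shoulder(pr_b), shoulder(pr_w) + 0.02)
})

test_that("hybrid reconstruction tracks its scatter input near interfaces", {
  ph_het <- slab_phantom(40, 1, 15, 20)
  ph_hom <- water_cube(40, 1)
  b <- small_beam()
  dc_het <- run_transport(ph_het, b, 1e5, seed = 10)
  dc_hom <- run_transport(ph_hom, b, 1e5, seed = 10)
  # swap in the homogeneous-water scatter cube (pure-convolution
  # behaviour): valley dose near the bone interface must change, since
  # the MC scatter sees the bone and the water bath does not
  dc_mix <- dc_het
  dc_mix$scatter <- dc_hom$scatter
  roi <- list(lo = c(18, 19, 13), hi = c(22, 21, 15))
  mg_h <- reconstruct_field(dc_het, b, ph_het, roi)
  mg_m <- reconstruct_field(dc_mix, b, ph_het, roi)
  v_h <- pvdr(extract_profile(mg_h, 14), collimator("planar"))$valley
  v_m <- pvdr(extract_profile(mg_m, 14), collimator("planar"))$valley
  expect_gt(abs(v_h - v_m) / v_h, 0.02)
  # while the engine reproduces its own scatter input exactly
  iz <- (14 - 13 - 1) * 2 + 1
  expect_equal(min(mg_h$dose[, 1, iz]) >= min(dc_het$scatter[19:22, 20, 14]),
               TRUE)
})

test_that("cross-fire assembly is linear and respects superposition", {
  ph <- water_cube(40, 1)
  bz <- small_beam(); bx <- beam_config("+x", square_field(2),
                                        collimator("planar"),
                                        mono_spectrum(100), 0.05)
  dcz <- run_transport(ph, bz, 5e4, seed = 11)
  dcx <- run_transport(ph, bx, 5e4, seed = 12)
  gz <- reconstruct_field(dcz, bz, ph, list(lo = c(18, 19, 18), hi = c(22, 21, 22)))
  gx <- reconstruct_field(dcx, bx, ph, list(lo = c(18, 18, 19), hi = c(22, 22, 21)))
  # single field: resampling onto its own grid is the identity
  self <- assemble_cross_fire(list(gz), spacing_mm = gz$spacing,
                              roi_mm = list(lo = c(18, 19, 19),
                                            hi = c(22, 21, 21)))
  pts <- cbind(seq(18.5, 21.5, by = 0.25), 20.2, 20.2)
  expect_equal(sample_micro_grid(self, pts), sample_micro_grid(gz, pts),
               tolerance = 0.005)
  # two orthogonal fields: dose adds linearly
  roi <- list(lo = c(19.2, 19.2, 19.2), hi = c(20.8, 20.8, 20.8))
  cf <- assemble_cross_fire(list(gz, gx), spacing_mm = c(0.005, 0.4, 0.1),
                            roi_mm = roi)
  pts2 <- as.matrix(expand.grid(seq(19.3, 20.7, by = 0.1), 20,
                                seq(19.3, 20.7, by = 0.1)))
  sz <- sample_micro_grid(gz, pts2); sx <- sample_micro_grid(gx, pts2)
  cc <- sample_micro_grid(cf, pts2)
  expect_equal(mean(cc), mean(sz + sx), tolerance = 0.02)
  # non-overlapping ROIs are refused
  expect_error(assemble_cross_fire(list(gz, gx), c(0.005, 1, 0.1),
                                   roi_mm = list(lo = c(0, 0, 0),
                                                 hi = c(0, 0, 0))),
               "overlap")
})
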