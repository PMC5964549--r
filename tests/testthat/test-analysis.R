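make_grid <- function(dose, bin_mm = 0.005, centre = 1) {
  micro_dose_grid(dose, axes = 1:3,
                  spacing_mm = c(bin_mm, 1, 0.5),
                  origin_mm = c(0, 0, 0),
                  meta = list(comb_centre_mm = centre))
}

test_that("profile extraction averages the right longitudinal slab", {
  d <- array(2, dim = c(400, 2, 4))
  g <- make_grid(d)
  pr <- extract_profile(g, 0.75)
  expect_equal(nrow(pr), 400)
  expect_true(all(pr$dose == 2))
  expect_error(extract_profile(g, 99), "outside")
})

test_that("PVDR estimator handles flat and ideal comb profiles", {
  col <- collimator("planar", 50, 400)
  u <- seq(-997.5, 997.5, by = 5)
  flat <- data.frame(position_um = u, dose = rep(7, length(u)))
  expect_equal(pvdr(flat, col)$pvdr, 1)
  # ideal comb: in-slit 8 Dp + Ds, valley Ds
  Dp <- 3; Ds <- 0.5
  comb <- ifelse(abs((u + 200) %% 400 - 200) <= 25, 8 * Dp + Ds, Ds)
  pv <- pvdr(data.frame(position_um = u, dose = comb), col)
  expect_equal(pv$peak, 8 * Dp + Ds)
  expect_equal(pv$valley, Ds)
  expect_equal(pv$pvdr, (8 * Dp + Ds) / Ds)
  short <- data.frame(position_um = u[abs(u) < 550],
                      dose = comb[abs(u) < 550])
  expect_error(pvdr(short, col), "3 period")
})

test_that("profile of a reconstructed water field is symmetric with the collimator period", {
  ph <- water_cube(40, 1)
  b <- small_beam()
  dc <- run_transport(ph, b, 1e5, seed = 13)
  # uniform coarse doses isolate the engine geometry from MC noise
  dc$primary[] <- 1e-11
  dc$scatter[] <- 1e-12
  mg <- reconstruct_field(dc, b, ph, list(lo = c(18, 19, 9), hi = c(22, 21, 11)))
  pr <- extract_profile(mg, 10)
  # fundamental spatial frequency at 1/pitch
  ctr <- abs(pr$position_um) <= 1000   # 400 bins = 5 periods
  sp <- Mod(fft(pr$dose[ctr] - mean(pr$dose[ctr])))
  expect_equal(which.max(sp[2:200]), 5)   # 5 cycles across 2 mm
  # symmetry about the beam centre
  d <- pr$dose[ctr]
  expect_lt(mean(abs(d - rev(d))) / mean(d), 1e-9)
})

test_that("DVH is an exact complementary CDF with the area identity", {
  # uniform dose: single step at d
  dv <- dvh(array(2.5, c(4, 4, 2)))
  expect_equal(dv$volume_fraction[dv$dose == 0], 1)
  expect_equal(dv$volume_fraction[dv$dose == 2.5], 1)
  expect_equal(dvh(array(2.5, c(4, 4, 2)),
                   dose_grid = c(0, 2.5, 2.6))$volume_fraction,
               c(1, 1, 0))
  # two-level dose: plateaus at 1, 0.5, 0
  v <- c(rep(1, 8), rep(3, 8))
  dv2 <- dvh(v, dose_grid = c(0, 0.5, 1, 2, 3, 3.5))
  expect_equal(dv2$volume_fraction, c(1, 1, 1, 0.5, 0.5, 0))
  # monotone non-increasing on arbitrary data
  set.seed(41)
  x <- rexp(1000)
  dv3 <- dvh(x)
  expect_true(all(diff(dv3$volume_fraction) <= 0))
  expect_equal(dv3$volume_fraction[1], 1)
  # area under the DVH equals the mean dose
  expect_equal(dvh_mean_dose(dv3), mean(x), tolerance = 1e-9)
  expect_error(dvh(x, mask = rep(FALSE, 1000)), "empty")
})

test_that("grid comparison reports signed relative differences", {
  a <- array(runif(64), c(4, 4, 4))
  z <- compare_grids(a, a)
  expect_equal(z$max, 0)
  z2 <- compare_grids(1.02 * a, a)
  expect_equal(z2$mean, 0.02, tolerance = 1e-12)
  expect_equal(z2$max, 0.02, tolerance = 1e-12)
  expect_error(compare_grids(a, array(1, c(2, 2, 2))), "geometry")
})

test_that("PVDR decreases when the electron range is artificially doubled", {
  nu <- fluence_pattern(collimator("planar"), 5)
  kern <- polychromatic_kernel(mono_spectrum(100), the_lib$water,
                               the_model, 1)
  kern2 <- kern
  kern2$components$sigma <- kern$components$sigma * 2
  kern2$max_sigma <- kern$max_sigma * 2
  u <- ((1:80) - 0.5 - 40) * 5
  mkprof <- function(M) {
    up <- seq(-997.5, 997.5, by = 5)
    data.frame(position_um = up,
               dose = 0.1 + M[(round(up / 5 - 0.5 + 0.5) %% 80) + 1])
  }
  M1 <- modulation_function(kern, nu)
  M2 <- modulation_function(kern2, nu)
  col <- collimator("planar")
  shift <- function(M) c(M[41:80], M[1:40])  # slit centre to u = 0 raster
  p1 <- pvdr(mkprof(shift(M1)), col)$pvdr
  p2 <- pvdr(mkprof(shift(M2)), col)$pvdr
  expect_gt(p1, p2)
})
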