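# sigma for a 50 keV electron in water: 43 um
sig50 <- csda_range(the_model, the_lib$water, 50)

test_that("3D kernel closed form: plug-in value, support, mass integral", {
  E0 <- 50
  r <- sig50 / 2
  expect_equal(kernel_3d(r, E0, sig50),
               E0 * (1 - 0.415) / (4 * pi * sig50 * r^2) * 2^0.415)
  expect_identical(kernel_3d(1.1 * sig50, E0, sig50), 0)
  expect_error(kernel_3d(0, E0, sig50), "singular")
  m <- integrate(function(r) kernel_3d(r, E0, sig50) * 4 * pi * r^2,
                 0, sig50, rel.tol = 1e-10)$value
  expect_equal(m, E0, tolerance = 1e-8)
})

test_that("2D kernel equals the z-integral of the 3D kernel and conserves energy", {
  E0 <- 50
  for (f in c(0.1, 0.5, 0.9)) {
    s <- f * sig50
    zint <- 2 * integrate(function(z) kernel_3d(sqrt(s^2 + z^2), E0, sig50),
                          0, sqrt(sig50^2 - s^2), rel.tol = 1e-10)$value
    expect_equal(kernel_2d(s, E0, sig50), zint, tolerance = 1e-5)
  }
  m <- integrate(Vectorize(function(s) kernel_2d(s, E0, sig50) * 2 * pi * s),
                 0, sig50, rel.tol = 1e-9)$value
  expect_equal(m, E0, tolerance = 1e-6)
  expect_identical(kernel_2d(sig50, E0, sig50), 0)
})

test_that("1D kernel equals the x,z-integral of the 3D kernel and conserves energy", {
  E0 <- 50
  # reduce via the (already validated) 2D kernel: K1(y) = int K2(s) dx
  for (f in c(0.2, 0.5, 0.8)) {
    y <- f * sig50
    xint <- 2 * integrate(Vectorize(function(x)
      kernel_2d(sqrt(x^2 + y^2), E0, sig50)),
      0, sqrt(sig50^2 - y^2), rel.tol = 1e-9)$value
    expect_equal(kernel_1d(y, E0, sig50), xint, tolerance = 1e-5)
  }
  m <- 2 * integrate(Vectorize(function(y) kernel_1d(y, E0, sig50)),
                     0, sig50, rel.tol = 1e-9)$value
  expect_equal(m, E0, tolerance = 1e-6)
  expect_identical(kernel_1d(sig50, E0, sig50), 0)
  expect_error(kernel_1d(0, E0, sig50), "diverges")
})

test_that("kernels are nonnegative and monotone on the regular part of the support", {
  E0 <- 30
  sig <- csda_range(the_model, the_lib$water, E0)
  d <- seq(0.05, 0.8, length.out = 40) * sig
  for (fn in list(kernel_1d, kernel_2d, kernel_3d)) {
    v <- fn(d, E0, sig)
    expect_true(all(v >= 0))
    expect_true(all(diff(v) < 0))
  }
})

test_that("cell-integrated kernels conserve mass and nest under refinement", {
  k1 <- mono_electron_kernel(100, the_lib$water, the_model, 1)
  ck <- cell_integrated_kernel(k1, 5)
  expect_equal(sum(ck$values) * 5e-4, 100, tolerance = 1e-6)
  # refining by 5 partitions each coarse bin exactly
  ckf <- cell_integrated_kernel(k1, 1)
  for (j in c(0, 3, 10)) {
    coarse <- ck$values[ck$offsets == j]
    fine <- ckf$values[ckf$offsets %in% (5 * j + -2:2)]
    expect_equal(mean(fine), coarse, tolerance = 1e-9)
  }
  # pitch wider than the range: single delta bin with the full mass
  kd <- mono_electron_kernel(2, the_lib$water, the_model, 1)
  ckd <- cell_integrated_kernel(kd, 50)
  expect_equal(length(ckd$values), 1L)
  expect_equal(ckd$values * 50e-4, 2, tolerance = 1e-9)
})

test_that("2D cell integration matches brute-force quadrature off-centre", {
  k2 <- mono_electron_kernel(30, the_lib$water, the_model, 2)
  ck <- cell_integrated_kernel(k2, 5)
  h <- 5e-4
  expect_equal(sum(ck$values) * h^2, 30, tolerance = 1e-6)
  sig <- csda_range(the_model, the_lib$water, 30)
  for (off in list(c(3, 0), c(1, 1))) {
    v <- ck$values[ck$offsets == off[1], ck$offsets == off[2]]
    bf <- integrate(Vectorize(function(x)
      integrate(Vectorize(function(y) kernel_2d(sqrt(x^2 + y^2), 30, sig)),
                (off[2] - 0.5) * h, (off[2] + 0.5) * h,
                rel.tol = 1e-9)$value),
      (off[1] - 0.5) * h, (off[1] + 0.5) * h, rel.tol = 1e-9)$value / h^2
    expect_equal(v, bf, tolerance = 1e-4)
  }
})

test_that("polychromatic weighting collapses to the right monochromatic limits", {
  w <- the_lib$water
  # no photoelectric coefficient: pure Compton component at E0 = p E
  wc <- w; wc$tau[] <- 0
  kp <- polychromatic_kernel(mono_spectrum(100), wc, the_model, 1)
  expect_equal(nrow(kp$components), 1L)
  expect_equal(kp$components$E0,
               compton_mean_transfer_fraction(100) * 100)
  # no Compton coefficient: pure photoelectron at E0 = E
  wp <- w; wp$sigma_compton[] <- 0
  kp2 <- polychromatic_kernel(mono_spectrum(100), wp, the_model, 1)
  expect_equal(kp2$components$E0, 100)
  expect_equal(kp2$mean_energy, 100)
  # two-line spectrum: mass integral is the f-weighted mean of the
  # component masses computed independently
  sp <- spectrum(c(50, 100), c(0.3, 0.7))
  kk <- polychromatic_kernel(sp, w, the_model, 1)
  m1 <- polychromatic_kernel(mono_spectrum(50), w, the_model, 1)$mean_energy
  m2 <- polychromatic_kernel(mono_spectrum(100), w, the_model, 1)$mean_energy
  expect_equal(kk$mean_energy, 0.3 * m1 + 0.7 * m2, tolerance = 1e-12)
  expect_error(polychromatic_kernel(spectrum(numeric(0), numeric(0)),
                                    w, the_model, 1))
})

test_that("CSDA sampling oracle reproduces the closed-form 3D kernel", {
  E0 <- 50
  or <- kernel_mc_oracle(E0, sig50, n = 1e4, seed = 3, n_shells = 40)
  expect_equal(sum(or$energy), E0, tolerance = 1e-9)   # full CSDA stop
  expect_true(all(or$r_hi <= sig50 + 1e-15))           # nothing beyond range
  shell_mass <- kernel_3d_mass(or$r_hi, E0, sig50) -
    kernel_3d_mass(or$r_lo, E0, sig50)
  analytic <- shell_mass / (4 / 3 * pi * (or$r_hi^3 - or$r_lo^3))
  # interior shells: pointwise agreement within the step discretisation
  i <- 2:38
  expect_equal(or$dose[i] / analytic[i], rep(1, length(i)),
               tolerance = 5e-3)
})
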