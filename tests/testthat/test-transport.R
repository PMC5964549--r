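test_that("Compton sampling respects kinematics and the Klein-Nishina law", {
  set.seed(31)
  E <- 200
  cs <- sample_compton(rep(E, 1e6))
  k <- E / 510.99895
  expect_true(all(cs$E_scattered >= E / (1 + 2 * k) - 1e-9))
  expect_true(all(cs$E_scattered <= E + 1e-9))
  expect_true(all(abs(cs$cos_theta) <= 1))
  # mean recoil energy vs the analytic value, within 3 standard errors
  recoil <- E - cs$E_scattered
  target <- compton_mean_transfer_fraction(E) * E
  se <- sd(recoil) / sqrt(length(recoil))
  expect_lt(abs(mean(recoil) - target), 3 * se)
  # angular distribution vs the numerically integrated KN density
  kn <- function(mu) {
    eps <- 1 / (1 + k * (1 - mu))
    eps^2 * (eps + 1 / eps - (1 - mu^2))
  }
  edges <- seq(-1, 1, by = 0.1)
  pexp <- vapply(seq_len(length(edges) - 1), function(i)
    integrate(kn, edges[i], edges[i + 1], rel.tol = 1e-10)$value,
    numeric(1))
  obs <- table(cut(cs$cos_theta, edges))
  chi <- chisq.test(obs, p = pexp / sum(pexp))
  expect_gt(chi$p.value, 0.001)
})

test_that("a beam that misses the phantom deposits nothing", {
  ph <- water_cube(40, 2)
  poly <- square_field(2)
  poly[, 1] <- poly[, 1] + 50          # field far outside the phantom
  b <- beam_config("+z", poly, collimator("open"), mono_spectrum(100), 0.5)
  dc <- run_transport(ph, b, 500, seed = 1, batches = 2)
  expect_equal(sum(dc$primary) + sum(dc$scatter), 0)
  expect_equal(dc$energy$escaped_keV, dc$energy$emitted_keV)
})

test_that("Rayleigh-only transport is elastic: zero energy deposited", {
  ph <- water_cube(40, 2)
  b <- small_beam(field_mm = 4)
  dc <- run_transport(ph, b, 2000, seed = 2, batches = 2,
                      disable = c("photoelectric", "compton"))
  expect_equal(sum(dc$primary) + sum(dc$scatter), 0)
  expect_equal(dc$energy$escaped_keV, dc$energy$emitted_keV,
               tolerance = 1e-12)
})

test_that("energy bookkeeping closes and deposition never exceeds emission", {
  ph <- water_cube(40, 1)
  b <- small_beam()
  dc <- run_transport(ph, b, 5e4, seed = 3)
  en <- dc$energy
  expect_equal(en$primary_keV + en$scatter_keV + en$escaped_keV,
               en$emitted_keV, tolerance = 1e-6 * en$emitted_keV)
  expect_lte(en$primary_keV + en$scatter_keV, en$emitted_keV)
  expect_true(all(dc$primary >= 0) && all(dc$scatter >= 0))
  # reproducibility for fixed (seed, batches)
  dc2 <- run_transport(ph, b, 5e4, seed = 3)
  expect_identical(dc$primary, dc2$primary)
  expect_identical(dc$scatter, dc2$scatter)
})

test_that("first-collision kerma matches the analytic attenuation law", {
  ph <- water_cube(40, 1)
  b <- beam_config("+z", square_field(10), collimator("open"),
                   mono_spectrum(100), 0.25)
  n <- 1e6
  dc <- run_transport(ph, b, n, seed = 4, batches = 4,
                      forced_single = TRUE, disable = "rayleigh")
  w <- the_lib$water
  ma <- mass_attenuation(w, 100)
  mu <- (ma$photoelectric + ma$compton) / 10       # 1/mm at rho = 1
  p <- compton_mean_transfer_fraction(100)
  epere <- 100 * (ma$photoelectric + p * ma$compton) /
    (ma$photoelectric + ma$compton)                # keV per interaction
  # energy per depth slab over the full field (10 x 10 central voxels)
  infield <- 16:25
  slab_gy <- vapply(1:10, function(iz)
    sum(dc$primary[infield, infield, iz]), numeric(1))
  slab_keV <- slab_gy / 1.602176634e-13 * 1e-3 * n   # Gy -> keV (1 cm3 voxels)
  z <- 0:10
  expected <- n * (exp(-mu * z[-11]) - exp(-mu * z[-1])) * epere
  expect_equal(slab_keV / expected, rep(1, 10), tolerance = 0.02)
  # exponential depth law (goodness of fit on slab energies)
  chi <- chisq.test(slab_keV / epere,
                    p = expected / epere / sum(expected / epere))
  expect_gt(chi$p.value, 0.001)
  # log-linear slope equals -mu within 2%
  slope <- coef(lm(log(slab_keV) ~ I(z[-11] + 0.5)))[2]
  expect_equal(unname(slope), -mu, tolerance = 0.02)
})

test_that("batch variance scales as 1/N (doubling histories halves it)", {
  ph <- water_cube(40, 2)
  b <- small_beam(field_mm = 4)
  dc1 <- run_transport(ph, b, 4e4, seed = 5, batches = 10)
  dc2 <- run_transport(ph, b, 8e4, seed = 6, batches = 10)
  ctr <- 9:12
  v1 <- dc1$scatter_ci95[ctr, ctr, 3:8]^2
  v2 <- dc2$scatter_ci95[ctr, ctr, 3:8]^2
  ratio <- mean(v1) / mean(v2)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("scatter-to-primary ratio builds up with depth", {
  ph <- water_cube(160, 10)
  b <- beam_config("+z", square_field(20), collimator("open"),
                   mono_spectrum(100), 0.5)
  dc <- run_transport(ph, b, 2e5, seed = 5)
  ratio <- vapply(1:5, function(k)
    mean(dc$scatter[8:9, 8:9, k]) / mean(dc$primary[8:9, 8:9, k]),
    numeric(1))
  expect_true(all(diff(ratio) > 0))
})

test_that("beam direction mapping attenuates along the beam axis", {
  ph <- water_cube(40, 2)
  b <- beam_config("+x", square_field(8), collimator("open"),
                   mono_spectrum(100), 0.5)
  dc <- run_transport(ph, b, 5e4, seed = 7)
  prof_x <- vapply(1:20, function(i)
    mean(dc$primary[i, 9:12, 9:12]), numeric(1))
  expect_gt(prof_x[1], prof_x[20] * 1.3)      # attenuation along +x
  fit <- coef(lm(log(prof_x) ~ I((1:20) * 2)))[2]
  mu_mm <- linear_attenuation(the_lib$water, 100)$total / 10
  expect_equal(unname(fit), -mu_mm, tolerance = 0.15)
})
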