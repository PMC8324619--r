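test_that("energy window widths follow the scanner convention", {
  expect_equal(window_width(photopeak_window()), 28.1)
  expect_equal(window_width(scatter_window()), 12.0)
  expect_equal(window_width(energy_window(99, 0)), 0)
  expect_error(energy_window(-1, 0.1), "positive")
})

test_that("PSF model reproduces the LEHR resolution anchor", {
  phys <- physics_model()
  expect_equal(psf_sigma(100, phys)$fwhm, 7.4)
  expect_equal(psf_sigma(0, phys)$fwhm, 3.8)
  expect_equal(psf_sigma(100, phys)$sigma, 7.4 / sqrt(8 * log(2)))
  expect_error(psf_sigma(-1, phys), "non-negative")
})

test_that("protocols carry the study's angular sampling and timing", {
  cl <- clinical_protocol(); ne <- nema_protocol()
  expect_identical(cl$n_projections, 60L)
  expect_equal(cl$angle_step, 6)
  expect_identical(ne$n_projections, 120L)
  expect_equal(ne$angle_step, 3)
  expect_equal(cl$T, 1200)
  expect_equal(ne$T, 1200)
})

test_that("projection of a point source conserves counts at every angle", {
  grid <- voxel_grid(c(32, 32, 4))
  act <- array(0, grid$shape); act[16, 16, 2] <- 40  # kBq/ml, on-center voxel
  real <- fake_real(act, array(0, grid$shape), grid)
  proto <- acquisition_protocol(12, 100)
  phys <- physics_model(scatter_fraction = 0)
  ps <- forward_project(real, proto, phys, resolution_model = FALSE,
                        attenuation = FALSE)
  expected <- proto$dwell * phys$sensitivity[1] * 40 * grid$v_voxel * 1e-3
  sums <- apply(ps$photopeak, 3, sum)
  expect_equal(sums, rep(expected, 12), tolerance = 1e-9)
})

test_that("attenuation factors match an independent ray-marching oracle", {
  grid <- voxel_grid(c(8, 8, 1))
  mu <- array(0.154, grid$shape)
  act <- array(0, grid$shape); act[5, 5, 1] <- 10
  real <- fake_real(act, mu, grid)
  phys <- physics_model(scatter_fraction = 0)
  for (ang in c(0, 90, 180, 270)) {
    proto <- acquisition_protocol(1, 100)
    proto$angles_deg <- ang
    ps <- forward_project(real, proto, phys, resolution_model = FALSE,
                          attenuation = TRUE)
    oracle <- ray_march_oracle(act, mu, c(5, 5, 1), ang, grid$voxel_size) *
      proto$dwell * phys$sensitivity[1] * grid$v_voxel * 1e-3
    expect_equal(sum(ps$photopeak), oracle, tolerance = 1e-10)
  }
  # central source in a uniform cube: attenuation ~ exp(-mu L / 2)
  g9 <- voxel_grid(c(9, 9, 1))
  mu9 <- array(0.154, g9$shape)
  a9 <- array(0, g9$shape); a9[5, 5, 1] <- 10
  proto <- acquisition_protocol(1, 100); proto$angles_deg <- 0
  ps <- forward_project(fake_real(a9, mu9, g9), proto, phys,
                        resolution_model = FALSE, attenuation = TRUE)
  analytic <- 10 * exp(-0.154 * (9 * 0.221) / 2) *
    proto$dwell * phys$sensitivity[1] * g9$v_voxel * 1e-3
  expect_equal(sum(ps$photopeak), analytic, tolerance = 1e-10)
})

test_that("expected counts scale linearly with dwell and sensitivity", {
  real <- toy_phantom(voxel_grid(c(32, 32, 4)))
  phys <- physics_model(scatter_fraction = 0)
  p1 <- forward_project(real, acquisition_protocol(6, 10), phys)
  p2 <- forward_project(real, acquisition_protocol(6, 20), phys)
  expect_equal(2 * p1$photopeak, p2$photopeak, tolerance = 1e-12)
  phys2 <- physics_model(sensitivity = 2 * 72.3, scatter_fraction = 0)
  p3 <- forward_project(real, acquisition_protocol(6, 10), phys2)
  expect_equal(2 * p1$photopeak, p3$photopeak, tolerance = 1e-12)
})

test_that("scatter-free simulation has an empty scatter window", {
  real <- toy_phantom(voxel_grid(c(32, 32, 4)))
  phys <- physics_model(scatter_fraction = 0)
  ps <- simulate_acquisition(real, acquisition_protocol(6, 10), phys, seed = 3)
  expect_true(all(ps$scatter_window == 0))
})

test_that("both protocols collect comparable total statistics in equal time", {
  real <- toy_phantom()
  phys <- physics_model()
  cl <- simulate_acquisition(real, clinical_protocol(), phys, seed = 11)
  ne <- simulate_acquisition(real, nema_protocol(), phys, seed = 12)
  tot_cl <- sum(cl$photopeak); tot_ne <- sum(ne$photopeak)
  expect_lt(abs(tot_cl - tot_ne), 3 * sqrt((tot_cl + tot_ne) / 2) + 0.01 * tot_cl)
})

test_that("acquisition noise is reproducible from the seed", {
  real <- toy_phantom(voxel_grid(c(32, 32, 4)))
  phys <- physics_model()
  proto <- acquisition_protocol(6, 10)
  a <- simulate_acquisition(real, proto, phys, seed = 5)
  b <- simulate_acquisition(real, proto, phys, seed = 5)
  d <- simulate_acquisition(real, proto, phys, seed = 6)
  expect_identical(a$photopeak, b$photopeak)
  expect_identical(a$scatter_window, b$scatter_window)
  expect_false(identical(a$photopeak, d$photopeak))
  expect_true(all(a$photopeak == floor(a$photopeak)))
  expect_true(all(a$photopeak >= 0))
})

test_that("noisy realizations average to the noise-free sinogram", {
  real <- toy_phantom(voxel_grid(c(32, 32, 2)))
  phys <- physics_model()
  proto <- acquisition_protocol(8, 30)
  nf <- simulate_acquisition(real, proto, phys, noise = FALSE)
  n_rep <- 200
  acc <- array(0, dim(nf$photopeak))
  for (r in seq_len(n_rep))
    acc <- acc + simulate_acquisition(real, proto, phys, seed = 100 + r)$photopeak
  mu <- nf$photopeak
  sel <- mu > 5
  z <- (acc[sel] / n_rep - mu[sel]) / sqrt(mu[sel] / n_rep)
  # standardized residuals behave like N(0,1); the mean of n z-scores has
  # standard error 1/sqrt(n)
  expect_lt(abs(mean(z)), 4 / sqrt(length(z)))
  expect_lt(abs(mean(z^2) - 1), 0.15)
})

test_that("invalid physics settings are rejected", {
  expect_error(physics_model(scatter_fraction = 1), "scatter_fraction")
  expect_error(physics_model(sensitivity = 0), "positive")
  expect_error(physics_model(k_true = 0), "positive")
})
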