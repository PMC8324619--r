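test_that("SCF to k conversion reproduces the study multipliers", {
  expect_equal(scf_to_k(1.10, report = TRUE), 0.470)
  expect_equal(scf_to_k(0.41, report = TRUE), 0.175)
  expect_equal(scf_to_k(0), 0)
  expect_error(scf_to_k(1, w_pk = 0), "positive")
  # round trip through the Jaszczak multiplier
  expect_equal(k_to_scf(scf_to_k(0.73)), 0.73, tolerance = 1e-12)
  sp <- scatter_params(scf = 1.10)
  expect_equal(sp$k, sp$scf * sp$w_sc / sp$w_pk, tolerance = 1e-12)
  expect_error(scatter_params(scf = 1, k = 1), "exactly one")
})

test_that("DEW scatter estimate is linear in k and exact at k_true", {
  s <- array(runif(60, 0, 20), c(5, 4, 3))
  expect_true(all(dew_scatter_estimate(s, 0) == 0))
  expect_equal(dew_scatter_estimate(s, 0.35), 2 * dew_scatter_estimate(s, 0.175))
  expect_error(dew_scatter_estimate(s, -0.1), "non-negative")
  # simulator self-consistency: k_true * expected scatter window equals the
  # simulated scatter-in-peak bin for bin
  real <- toy_phantom(voxel_grid(c(32, 32, 4)))
  phys <- physics_model()
  ps <- simulate_acquisition(real, acquisition_protocol(6, 10), phys,
                             noise = FALSE)
  expect_equal(dew_scatter_estimate(ps$scatter_window, phys$k_true),
               ps$scatter_in_peak, tolerance = 1e-12)
})

test_that("OSEM with one subset matches a dense-matrix MLEM oracle", {
  dims <- c(16, 16, 1)
  grid <- voxel_grid(dims)
  mu <- array(0.02, dims)
  angs <- seq(0, 360, length.out = 9)[1:8]
  phys <- physics_model(radius_of_rotation = 80)
  proto <- acquisition_protocol(8, 150)
  proto$angles_deg <- angs
  # explicit system matrix from unit basis vectors through the projector
  A <- sapply(seq_len(prod(dims)), function(i) {
    e <- array(0, dims); e[i] <- 1
    as.vector(qspect:::cpp_project(e, mu, dims, angs * pi / 180, grid$voxel_size,
                                   phys$radius_of_rotation, phys$psf_fwhm_at_0,
                                   phys$psf_fwhm_slope, TRUE, TRUE, 1 / 8))
  })
  xt <- array(0, dims); xt[6:10, 6:10, 1] <- 2
  y <- as.vector(A %*% as.vector(xt))
  # independently coded MLEM: x <- x / A^T 1 * A^T (y / A x)
  xm <- rep(1, ncol(A)); sj <- colSums(A)
  for (it in 1:5) {
    f <- as.vector(A %*% xm)
    r <- ifelse(f > 0, y / f, 0)
    xm <- ifelse(sj > 0, xm * as.vector(crossprod(A, r)) / sj, 0)
  }
  ps <- fake_projections(array(y, c(16, 1, 8)), proto, phys, grid)
  rv <- osem(ps, recon_params(5, 1), mu = mu, support = array(TRUE, dims))
  expect_equal(max(abs(rv$values - array(xm, dims)) / pmax(abs(xm), 1e-8)), 0,
               tolerance = 1e-10)
  expect_true(all(rv$values >= 0))
})

test_that("subset partition and degenerate data are validated", {
  real <- toy_phantom(voxel_grid(c(32, 32, 2)))
  phys <- physics_model()
  ps <- simulate_acquisition(real, clinical_protocol(), phys, seed = 1)
  expect_error(osem(ps, recon_params(1, 7), mu = real$mu), "evenly divide")
  ps0 <- ps; ps0$photopeak[] <- 0
  expect_warning(rv0 <- osem(ps0, recon_params(1, 10), mu = real$mu),
                 "all-zero")
  expect_true(all(rv0$values == 0))
})

test_that("sphere estimate decreases with SCF; background is stable in iterations", {
  grid <- voxel_grid(c(64, 64, 8))
  real <- toy_phantom(grid)
  phys <- physics_model()
  ps <- simulate_acquisition(real, acquisition_protocol(20, 60), phys,
                             noise = FALSE)
  qf <- compute_qf(72.3, 1200, grid$v_voxel)
  means <- vapply(c(0, 0.41, 1.10), function(scf) {
    prm <- recon_params(4, 10, scatter = if (scf > 0) scatter_params(scf = scf))
    rv <- counts_to_ac(osem(ps, prm, mu = real$mu), qf)
    voi_stats(rv, real$voi_labels, 1)$mean_ac
  }, numeric(1))
  expect_true(all(diff(means) < 0))  # more scatter removed, lower estimate
  # quantitative-convergence regime: background mean insensitive to updates
  bg <- vapply(c(4, 12, 24), function(it) {
    prm <- recon_params(it, 10, scatter = scatter_params(scf = 0.41))
    rv <- counts_to_ac(osem(ps, prm, mu = real$mu), qf)
    voi_stats(rv, real$voi_labels, 2)$mean_ac
  }, numeric(1))
  expect_lt(diff(range(bg)) / mean(bg), 0.02)
  # sphere recovery grows with updates on noise-free data
  sph <- vapply(c(2, 24), function(it) {
    prm <- recon_params(it, 10, scatter = scatter_params(scf = 0.41))
    rv <- counts_to_ac(osem(ps, prm, mu = real$mu), qf)
    voi_stats(rv, real$voi_labels, 1)$mean_ac
  }, numeric(1))
  expect_gt(sph[2], sph[1])
})

test_that("Butterworth filter has unit DC gain and half-power cutoff", {
  vol <- array(5, c(16, 16, 8))
  expect_equal(butterworth3d(vol, 0.5, 10), vol, tolerance = 1e-10)
  expect_error(butterworth3d(vol, 0, 10), "positive")
  # a pure cosine exactly at the cutoff frequency is attenuated to 1/2
  n <- 32; dx <- 2.21
  kk <- 4
  fc <- kk / (n * dx / 10)
  xline <- cos(2 * pi * kk * (0:(n - 1)) / n)
  vol2 <- array(rep(xline, times = n * 4), c(n, n, 4))
  filt <- butterworth3d(vol2, fc, 10, voxel_size = dx)
  expect_equal(max(abs(filt)), 0.5, tolerance = 1e-6)
})

test_that("Butterworth noise suppression matches the DFT-domain prediction", {
  set.seed(99)
  n <- 24
  vol <- array(rnorm(n^3), c(n, n, n))
  filt <- butterworth3d(vol, 0.5, 10)
  # white-noise variance shrinks by mean(H^2); rebuild H independently
  dx_cm <- 0.221
  f <- ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n) / (n * dx_cm)
  fr <- sqrt(outer(outer(f^2, f^2, `+`), f^2, `+`))
  H <- 1 / (1 + (fr / 0.5)^20)
  expect_equal(var(as.vector(filt)) / var(as.vector(vol)), mean(H^2),
               tolerance = 0.01)
})

test_that("counts to activity conversion is an exact invertible scaling", {
  grid <- voxel_grid(c(8, 8, 2))
  rv <- structure(list(values = array(runif(128), c(8, 8, 2)),
                       units = "counts",
                       params = recon_params(1, 1), grid = grid),
                  class = "recon_volume")
  # S*T*V = 1: counts numerically equal MBq/ml, i.e. 1000x kBq/ml
  qf1 <- compute_qf(10, 10, 0.01)
  expect_equal(qf1, 1)
  ac <- counts_to_ac(rv, qf1)
  expect_equal(ac$values, rv$values * 1000)
  expect_identical(ac$units, "kBq/ml")
  expect_error(counts_to_ac(ac, qf1), "already")
  back <- ac$values / (qf1 * 1000)
  expect_equal(back, rv$values, tolerance = 1e-12)
  rv0 <- rv; rv0$values[] <- 0
  expect_true(all(counts_to_ac(rv0, 0.5)$values == 0))
  expect_error(counts_to_ac(rv, 0), "positive")
})
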