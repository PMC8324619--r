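# Shared fixtures, all generated in code.

# compact hot-sphere phantom: one sphere in a small rounded-rectangle water
# tank, warm background, no lung insert; sphere and background VOI shrink to
# fit thin grids
toy_phantom <- function(grid = voxel_grid(c(64, 64, 8)),
                        sphere_ac = 85.1, background_ac = 10.6) {
  zhalf <- grid$shape[3] * grid$voxel_size / 2
  d <- min(16, floor(2 * zhalf))
  bg_r <- min((2 * 3 / (4 * pi))^(1 / 3) * 10, zhalf - 0.01)
  spec <- phantom_spec(
    sphere_diameters = max(d, 0.1),
    sphere_azimuth_deg = 0,
    sphere_ring_radius = 20,
    sphere_ac = sphere_ac, background_ac = background_ac,
    lung_insert_diameter = 0,
    body = list(width = 120, height = 100, corner_radius = 40, length = 100),
    background_voi_volume = 4 / 3 * pi * bg_r^3 / 1000,
    background_voi_center = c(-25, 0, 0))
  build_phantom(spec, grid)
}

# wrap bare arrays as a phantom realization (for projector-level tests)
fake_real <- function(activity, mu, grid) {
  structure(list(activity = activity, mu = mu,
                 voi_labels = array(0L, dim(activity)),
                 spec = NULL, grid = grid),
            class = "phantom_realization")
}

# wrap a sinogram as a projection_set (for reconstruction-level tests)
fake_projections <- function(photopeak, protocol, physics, grid,
                             scatter = NULL) {
  structure(list(photopeak = photopeak,
                 scatter_window = scatter %||% array(0, dim(photopeak)),
                 angles_deg = protocol$angles_deg,
                 protocol = protocol, physics = physics, grid = grid,
                 noise_free = TRUE),
            class = "projection_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent axis-aligned ray-marching oracle: expected projection value of
# a single source voxel, walking voxel by voxel toward the detector and
# accumulating mu (half weight for the source voxel itself)
ray_march_oracle <- function(activity, mu, src, angle_deg, voxel_mm) {
  d <- dim(mu)
  step <- switch(as.character(angle_deg %% 360),
                 "0"   = c(0L, 1L),   # detector on the +y side
                 "90"  = c(-1L, 0L),
                 "180" = c(0L, -1L),
                 "270" = c(1L, 0L),
                 stop("oracle handles axis-aligned angles only"))
  i <- src[1]; j <- src[2]; z <- src[3]
  path <- 0.5 * mu[i, j, z]
  repeat {
    i <- i + step[1]; j <- j + step[2]
    if (i < 1 || j < 1 || i > d[1] || j > d[2]) break
    path <- path + mu[i, j, z]
  }
  activity[src[1], src[2], src[3]] * exp(-path * voxel_mm / 10)
}
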