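test_that("protocol grid expands to the 16 study cells", {
  g <- protocol_grid()
  expect_equal(nrow(g), 16)
  expect_equal(anyDuplicated(g$protocol_id), 0L)
  expect_equal(sum(g$postfilter), 4)   # diagnostic 2i/10s cells
  expect_equal(sum(!g$postfilter), 12) # quantitative cells
  expect_setequal(unique(g$acquisition), c("clinical", "nema"))
  expect_setequal(unique(g$scf), c(0.41, 1.10))
  expect_true(all(g$postfilter == (g$iteration_set == "2i10s")))
  expect_equal(sort(unique(g$iterations * g$subsets)), c(20, 40, 75, 240))
})

toy_config <- function() {
  grid <- voxel_grid(c(48, 48, 6))
  spec <- phantom_spec(
    sphere_diameters = 12, sphere_azimuth_deg = 0, sphere_ring_radius = 20,
    lung_insert_diameter = 0,
    body = list(width = 120, height = 100, corner_radius = 40, length = 100),
    background_voi_volume = 0.5, background_voi_center = c(-25, 0, 0))
  study_config(spec = spec, grid = grid,
               iteration_sets = list("2i10s" = c(2, 10), "4i10s" = c(4, 10)),
               calib = calibration_constants(72.3, 72.3,
                                             v_voxel = grid$v_voxel))
}

test_that("grid runs are deterministic given the seed", {
  cfg <- toy_config()
  r1 <- run_grid(cfg, seed = 3)
  r2 <- run_grid(cfg, seed = 3)
  r3 <- run_grid(cfg, seed = 4)
  expect_identical(r1$metrics, r2$metrics)
  expect_false(identical(r1$metrics$mean_ac, r3$metrics$mean_ac))
  expect_equal(r1$n_failed, 0)
  # 2 acquisitions x 2 iteration sets x 2 SCFs, one row per VOI (2 VOIs)
  expect_equal(nrow(r1$metrics), 8 * 2)
  # byte-identical CSV output
  d1 <- tempfile(); d2 <- tempfile()
  write_grid_results(r1, d1, seed = 3)
  write_grid_results(r2, d2, seed = 3)
  expect_identical(readLines(file.path(d1, "metrics.csv")),
                   readLines(file.path(d2, "metrics.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
})

test_that("effect summary is all-zero when protocols are identical", {
  g <- protocol_grid()
  vois <- data.frame(voi = c("sphere_37mm", "background"),
                     diameter_mm = c(37, NA))
  records <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    cbind(g[rep(i, 2), ], vois,
          n_voxels = 10, mean_ac = c(70, 11), sd = c(3, 1.5),
          hsrc = c(70 / 85.1, NA), snr = c((70 - 11) / 1.5, NA),
          noise_pct = c(NA, 100 * 1.5 / 11),
          delta_ac = 0, delta_ac_pct = 0, row.names = NULL)
  }))
  eff <- summarize_effects(records)
  expect_equal(nrow(eff), 5)
  expect_true(all(eff$delta_ac == 0))
  expect_true(all(eff$delta_hsrc == 0))
  expect_true(all(eff$delta_snr == 0))
  expect_true(all(eff$delta_noise == 0))
  expect_true(all(eff$p_ac == 1))
  expect_identical(attr(eff, "reference"), "clinical_2i10s_scf1.10_pf")
  expect_error(summarize_effects(records, reference = "missing"), "not found")
})

test_that("panels built from records are complete sphere-by-protocol matrices", {
  g <- protocol_grid()
  records <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    cbind(g[rep(i, 3), ],
          data.frame(voi = c("sphere_10mm", "sphere_37mm", "background"),
                     diameter_mm = c(10, 37, NA),
                     hsrc = c(0.2 + i / 100, 0.8 + i / 100, NA)),
          row.names = NULL)
  }))
  pan <- panel_from_records(records, "hsrc")
  expect_s3_class(pan, "metric_panel")
  expect_equal(dim(pan$values), c(2, 16))
  expect_equal(pan$values["sphere_37mm", "clinical_4i10s_scf0.41"],
               records$hsrc[records$protocol_id == "clinical_4i10s_scf0.41" &
                              records$voi == "sphere_37mm"])
})

test_that("configuration round-trips through YAML", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "phantom:",
    "  sphere_diameters: [16]",
    "  sphere_azimuth_deg: [0]",
    "  sphere_ring_radius: 20",
    "  lung_insert_diameter: 0",
    "  body: {width: 120, height: 100, corner_radius: 40, length: 100}",
    "  background_voi_volume: 2",
    "  background_voi_center: [-25, 0, 0]",
    "grid:",
    "  shape: [48, 48, 6]",
    "physics:",
    "  scatter_fraction: 0.25",
    "scfs: [0.41, 1.10]"), yml)
  cfg <- read_config(yml)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$grid$shape, c(48L, 48L, 6L))
  expect_equal(cfg$physics$scatter_fraction, 0.25)
  expect_equal(cfg$spec$sphere_diameters, 16)
})

test_that("volumes round-trip through NIfTI and raw float32", {
  grid <- voxel_grid(c(12, 10, 4))
  vol <- array(runif(480), grid$shape)
  nii <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, grid, nii)
  back <- RNifti::readNifti(nii)
  expect_equal(array(as.numeric(back), grid$shape), vol, tolerance = 1e-6)
  raw <- tempfile(fileext = ".f32")
  write_volume_raw(vol, grid, raw, units = "kBq/ml")
  meta <- jsonlite::read_json(paste0(raw, ".json"), simplifyVector = TRUE)
  expect_equal(meta$shape, grid$shape)
  con <- file(raw, "rb")
  vals <- readBin(con, numeric(), n = 480, size = 4, endian = "little")
  close(con)
  expect_equal(array(vals, grid$shape), vol, tolerance = 1e-6)
})
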