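#' Study configuration
#'
#' Bundles everything needed to run the protocol grid: phantom, grid,
#' physics, calibration and the reconstruction parameter sets. The default
#' reproduces the study layout: two acquisition protocols (clinical 60 x 20 s
#' and NEMA 120 x 10 s), four iteration sets (2i/10s, 4i/10s, 5i/15s,
#' 24i/10s), two scatter weighting factors (0.41 and 1.10), and the
#' Butterworth postfilter (0.5 cycles/cm, power 10) applied exactly to the
#' 2i/10s "diagnostic" reconstructions.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [voxel_grid()]; the default 144 x 144 x 32 slab covers all
#'   VOIs at the scanner's 2.21 mm pixel size while staying desk-fast (the
#'   2D slice-wise model makes axial truncation exact for the retained
#'   slices).
#' @param physics a [physics_model()].
#' @param scfs scatter weighting factors to examine.
#' @param iteration_sets named list of `c(iterations, subsets)`.
#' @param postfilter Butterworth settings applied to the diagnostic
#'   (2i/10s) reconstructions.
#' @param calib a [calibration_constants()] for quantitation; default uses
#'   the measured per-head sensitivities 71.7 and 72.8 cps/MBq (system mean
#'   72.3).
#' @return a `study_config` object.
#' @export
study_config <- function(spec = phantom_spec(),
                         grid = voxel_grid(c(144, 144, 32)),
                         physics = physics_model(),
                         scfs = c(0.41, 1.10),
                         iteration_sets = list(
                           "2i10s" = c(2, 10),
                           "4i10s" = c(4, 10),
                           "5i15s" = c(5, 15),
                           "24i10s" = c(24, 10)),
                         postfilter = list(cutoff = 0.5, power = 10),
                         calib = calibration_constants(71.7, 72.8)) {
  structure(list(spec = spec, grid = grid, physics = physics, scfs = scfs,
                 iteration_sets = iteration_sets, postfilter = postfilter,
                 calib = calib),
            class = "study_config")
}

#' Expand the protocol grid
#'
#' @param config a [study_config()].
#' @return data.frame with one row per protocol cell: `protocol_id`,
#'   `acquisition`, `iteration_set`, `iterations`, `subsets`, `scf`,
#'   `postfilter` (TRUE for the diagnostic 2i/10s cells). The default
#'   expands to 16 cells: 12 quantitative and 4 postfiltered diagnostic.
#' @export
protocol_grid <- function(config = study_config()) {
  g <- expand.grid(acquisition = c("clinical", "nema"),
                   iteration_set = names(config$iteration_sets),
                   scf = config$scfs,
                   stringsAsFactors = FALSE)
  g$iterations <- vapply(g$iteration_set, function(n) config$iteration_sets[[n]][1], numeric(1))
  g$subsets <- vapply(g$iteration_set, function(n) config$iteration_sets[[n]][2], numeric(1))
  g$postfilter <- g$iteration_set == "2i10s"
  g$protocol_id <- paste0(g$acquisition, "_", g$iteration_set, "_scf",
                          format(g$scf, trim = TRUE),
                          ifelse(g$postfilter, "_pf", ""))
  g[order(g$acquisition, g$iteration_set, g$scf),
    c("protocol_id", "acquisition", "iteration_set", "iterations",
      "subsets", "scf", "postfilter")]
}

#' Run the full protocol grid
#'
#' Simulates one noisy acquisition per acquisition protocol (the same
#' realization is shared by all its reconstructions, as in the physical
#' study where one scan is reconstructed many ways), reconstructs every
#' cell, quantifies with QF, and computes per-VOI metrics.
#'
#' @param config a [study_config()].
#' @param seed integer seed controlling all counting noise.
#' @param verbose print per-cell progress.
#' @return list with `metrics` (tidy data.frame: grid columns + one row per
#'   VOI) and `grid` (the protocol table).
#' @export
run_grid <- function(config = study_config(), seed = 1, verbose = FALSE) {
  real <- build_phantom(config$spec, config$grid)
  cells <- protocol_grid(config)
  protos <- list(clinical = clinical_protocol(), nema = nema_protocol())
  acqs <- list()
  for (an in unique(cells$acquisition)) {
    acqs[[an]] <- simulate_acquisition(real, protos[[an]], config$physics,
                                       seed = derive_seed(seed, match(an, names(protos))))
  }
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    res <- tryCatch({
      params <- recon_params(
        iterations = cell$iterations, subsets = cell$subsets,
        scatter = scatter_params(scf = cell$scf),
        postfilter = if (cell$postfilter) config$postfilter else NULL)
      rv <- osem(acqs[[cell$acquisition]], params, mu = real$mu)
      rv <- apply_postfilter(rv)
      rv <- counts_to_ac(rv, config$calib$qf)
      m <- compute_metrics(rv, real)
      cbind(cell[rep(1, nrow(m)), ], m, row.names = NULL)
    }, error = function(e) {
      warning("cell ", cell$protocol_id, " failed: ", conditionMessage(e))
      cbind(cell, data.frame(voi = NA, diameter_mm = NA, n_voxels = NA,
                             mean_ac = NA, sd = NA, hsrc = NA, snr = NA,
                             noise_pct = NA, delta_ac = NA,
                             delta_ac_pct = NA, row.names = NULL))
    })
    if (verbose) message("done: ", cell$protocol_id)
    out[[i]] <- res
  }
  metrics <- do.call(rbind, out)
  rownames(metrics) <- NULL
  list(metrics = metrics, grid = cells, n_failed = sum(is.na(metrics$mean_ac)))
}

default_reference_id <- function(metrics) {
  id <- metrics$protocol_id[metrics$acquisition == "clinical" &
                              metrics$iteration_set == "2i10s" &
                              metrics$scf == 1.10][1]
  if (is.na(id)) stop_invalid("reference protocol not present in records")
  id
}

#' Effect summaries against the clinical reference protocol
#'
#' Mirrors the study's effect tables: each parameter variation (SCF 0.41;
#' iteration sets 4i/10s, 5i/15s, 24i/10s; NEMA acquisition) is compared
#' against the clinical diagnostic reference (clinical, 2i/10s, SCF 1.10,
#' postfiltered), changing one parameter at a time. Deltas are reported for
#' the largest sphere (AC, HSRC, SNR) and the background (AC, noise);
#' p-values come from Holm-adjusted paired contrasts across the sphere VOIs.
#'
#' @param records the `metrics` data.frame from [run_grid()].
#' @param reference protocol_id of the reference cell; default the clinical
#'   2i/10s SCF 1.10 postfiltered cell.
#' @return data.frame with one row per parameter variation.
#' @export
summarize_effects <- function(records, reference = NULL) {
  reference <- reference %||% default_reference_id(records)
  if (!reference %in% records$protocol_id)
    stop_invalid("reference protocol '", reference, "' not found")
  ref_row <- records[records$protocol_id == reference, ][1, ]
  variations <- list(
    "SCF: 0.41" = list(acquisition = ref_row$acquisition,
                       iteration_set = ref_row$iteration_set, scf = 0.41),
    "Iteration set: 4i/10s" = list(acquisition = ref_row$acquisition,
                                   iteration_set = "4i10s", scf = ref_row$scf),
    "Iteration set: 5i/15s" = list(acquisition = ref_row$acquisition,
                                   iteration_set = "5i15s", scf = ref_row$scf),
    "Iteration set: 24i/10s" = list(acquisition = ref_row$acquisition,
                                    iteration_set = "24i10s", scf = ref_row$scf),
    "Acquisition: NEMA" = list(acquisition = "nema",
                               iteration_set = ref_row$iteration_set,
                               scf = ref_row$scf))
  largest <- max(records$diameter_mm, na.rm = TRUE)
  cell_id <- function(v) {
    sel <- records$acquisition == v$acquisition &
      records$iteration_set == v$iteration_set & records$scf == v$scf
    unique(records$protocol_id[sel])
  }
  ref_vals <- function(id) {
    sph <- records[records$protocol_id == id & !is.na(records$diameter_mm), ]
    bg <- records[records$protocol_id == id & records$voi == "background", ]
    list(sph = sph[order(sph$diameter_mm), ], bg = bg)
  }
  rv <- ref_vals(reference)
  rows <- lapply(names(variations), function(nm) {
    id <- cell_id(variations[[nm]])
    if (length(id) != 1) stop_invalid("variation ", nm, " not uniquely present")
    cv <- ref_vals(id)
    ls_ref <- rv$sph[rv$sph$diameter_mm == largest, ]
    ls_cmp <- cv$sph[cv$sph$diameter_mm == largest, ]
    # paired contrast across sphere VOIs, Holm-adjusted over the 3 metrics
    p_sph <- vapply(c("mean_ac", "hsrc", "snr"), function(metric) {
      d <- cv$sph[[metric]] - rv$sph[[metric]]
      if (all(d == 0)) 1 else t.test(d)$p.value
    }, numeric(1))
    p_holm <- holm_adjust(p_sph)
    data.frame(
      variation = nm, protocol_id = id,
      delta_ac = ls_cmp$mean_ac - ls_ref$mean_ac,
      delta_hsrc = ls_cmp$hsrc - ls_ref$hsrc,
      delta_snr = ls_cmp$snr - ls_ref$snr,
      p_ac = p_holm[1], p_hsrc = p_holm[2], p_snr = p_holm[3],
      delta_ac_bg = cv$bg$mean_ac - rv$bg$mean_ac,
      delta_noise = cv$bg$noise_pct - rv$bg$noise_pct)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  out
}

#' Build a metric panel (spheres x protocols) from grid records
#'
#' @param records the `metrics` data.frame from [run_grid()].
#' @param metric column name, e.g. "hsrc", "snr", "mean_ac".
#' @return a [metric_panel()] with sphere VOIs as blocks.
#' @export
panel_from_records <- function(records, metric = "hsrc") {
  sph <- records[!is.na(records$diameter_mm), ]
  ids <- unique(sph$protocol_id)
  dia <- sort(unique(sph$diameter_mm))
  m <- sapply(ids, function(id) {
    r <- sph[sph$protocol_id == id, ]
    r[[metric]][match(dia, r$diameter_mm)]
  })
  rownames(m) <- paste0("sphere_", dia, "mm")
  metric_panel(m)
}

#' HSRC (or SNR) versus sphere diameter curves
#'
#' Plots the recovery (or SNR) curve per protocol, diameter optionally
#' normalized to the system FWHM at 100 mm.
#'
#' @param records the `metrics` data.frame from [run_grid()].
#' @param metric "hsrc" or "snr".
#' @param protocol_ids subset of protocols to draw (default all).
#' @param normalize_fwhm divide the diameter axis by this FWHM in mm (NULL
#'   for plain mm).
#' @return invisibly, the plotted data in long form.
#' @export
plot_recovery_curves <- function(records, metric = "hsrc",
                                 protocol_ids = NULL, normalize_fwhm = 7.4) {
  sph <- records[!is.na(records$diameter_mm), ]
  if (!is.null(protocol_ids)) sph <- sph[sph$protocol_id %in% protocol_ids, ]
  xs <- if (is.null(normalize_fwhm)) sph$diameter_mm else sph$diameter_mm / normalize_fwhm
  ids <- unique(sph$protocol_id)
  cols <- grDevices::hcl.colors(max(3, length(ids)), "Dark 3")
  graphics::plot(range(xs), range(sph[[metric]]), type = "n",
                 xlab = if (is.null(normalize_fwhm)) "sphere diameter (mm)"
                 else "sphere diameter / FWHM",
                 ylab = toupper(metric))
  for (i in seq_along(ids)) {
    r <- sph[sph$protocol_id == ids[i], ]
    o <- order(r$diameter_mm)
    x <- if (is.null(normalize_fwhm)) r$diameter_mm[o] else r$diameter_mm[o] / normalize_fwhm
    graphics::lines(x, r[[metric]][o], col = cols[i], type = "b", pch = 16)
  }
  graphics::legend("bottomright", legend = ids, col = cols[seq_along(ids)],
                   lty = 1, cex = 0.6)
  invisible(sph)
}
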