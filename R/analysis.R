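#' VOI statistics
#'
#' Mean and standard deviation of all voxels carrying a VOI label. The SD is
#' the population form (divisor n): VOIs are exhaustively enumerated voxel
#' sets, not samples.
#'
#' @param vol a `recon_volume` in kBq/ml (or a bare numeric array).
#' @param labels integer VOI label volume.
#' @param voi_id label to evaluate.
#' @return list with `voi_id`, `mean_ac`, `sd`, `n_voxels`.
#' @export
voi_stats <- function(vol, labels, voi_id) {
  values <- if (inherits(vol, "recon_volume")) vol$values else vol
  sel <- labels == voi_id
  n <- sum(sel)
  if (n == 0) stop_invalid("VOI label ", voi_id, " not present")
  v <- values[sel]
  m <- mean(v)
  list(voi_id = voi_id, mean_ac = m,
       sd = sqrt(sum((v - m)^2) / n), n_voxels = n)
}

#' Hot-spot recovery coefficient
#'
#' `HSRC = AC_rec.sphere / AC_real.sphere`; values below 1 reflect
#' partial-volume losses.
#'
#' @param ac_rec_sphere mean reconstructed AC in the sphere (kBq/ml).
#' @param ac_real_sphere known true AC (kBq/ml, > 0).
#' @param report round half-away-from-zero to 2 decimals.
#' @return the recovery coefficient.
#' @export
hsrc <- function(ac_rec_sphere, ac_real_sphere, report = FALSE) {
  if (any(ac_real_sphere <= 0)) stop_invalid("true AC must be positive")
  r <- ac_rec_sphere / ac_real_sphere
  if (report) round_half_out(r, 2) else r
}

#' Signal-to-noise ratio of a hot sphere
#'
#' `SNR = (AC_rec.sphere - AC_rec.BG) / SD_rec.BG`; signed, so cold regions
#' give negative values.
#'
#' @param mean_sphere mean AC in the sphere.
#' @param mean_bg mean AC in the background VOI.
#' @param sd_bg SD of the background VOI (> 0).
#' @return the ratio.
#' @export
snr <- function(mean_sphere, mean_bg, sd_bg) {
  if (any(sd_bg <= 0)) stop_invalid("background SD must be positive for SNR")
  (mean_sphere - mean_bg) / sd_bg
}

#' Background image noise in percent
#'
#' `N = 100 * SD_rec.BG / AC_rec.BG` (coefficient of variation of the
#' background VOI).
#'
#' @param sd_bg background SD.
#' @param mean_bg background mean (> 0).
#' @return noise in percent.
#' @export
noise_pct <- function(sd_bg, mean_bg) {
  if (any(mean_bg <= 0)) stop_invalid("background mean must be positive")
  100 * sd_bg / mean_bg
}

#' Per-VOI metrics for one reconstruction
#'
#' Computes the full metrics record for a quantified reconstruction: per
#' sphere the mean AC, HSRC, SNR against the background VOI, and the AC
#' deviation from truth; for the background the mean AC and noise.
#'
#' @param rv a `recon_volume` in kBq/ml.
#' @param real the `phantom_realization` providing VOI labels and truth.
#' @return data.frame with one row per VOI (`voi` of the form `sphere_<d>mm`
#'   or `background`), columns `diameter_mm`, `n_voxels`, `mean_ac`, `sd`,
#'   `hsrc`, `snr`, `noise_pct`, `delta_ac`, `delta_ac_pct`.
#' @export
compute_metrics <- function(rv, real) {
  stopifnot(inherits(rv, "recon_volume"))
  if (!identical(rv$units, "kBq/ml"))
    stop_invalid("reconstruction must be quantified to kBq/ml first")
  spec <- real$spec
  nsph <- length(spec$sphere_diameters)
  labels <- real$voi_labels
  bg <- voi_stats(rv, labels, nsph + 1L)
  rows <- lapply(seq_len(nsph), function(s) {
    st <- voi_stats(rv, labels, s)
    data.frame(voi = paste0("sphere_", spec$sphere_diameters[s], "mm"),
               diameter_mm = spec$sphere_diameters[s],
               n_voxels = st$n_voxels,
               mean_ac = st$mean_ac, sd = st$sd,
               hsrc = hsrc(st$mean_ac, spec$sphere_ac),
               snr = snr(st$mean_ac, bg$mean_ac, bg$sd),
               noise_pct = NA_real_,
               delta_ac = st$mean_ac - spec$sphere_ac,
               delta_ac_pct = 100 * (st$mean_ac - spec$sphere_ac) / spec$sphere_ac)
  })
  bg_row <- data.frame(voi = "background", diameter_mm = NA_real_,
                       n_voxels = bg$n_voxels,
                       mean_ac = bg$mean_ac, sd = bg$sd,
                       hsrc = NA_real_, snr = NA_real_,
                       noise_pct = noise_pct(bg$sd, bg$mean_ac),
                       delta_ac = bg$mean_ac - spec$background_ac,
                       delta_ac_pct = if (spec$background_ac > 0)
                         100 * (bg$mean_ac - spec$background_ac) / spec$background_ac
                       else NA_real_)
  out <- rbind(do.call(rbind, rows), bg_row)
  rownames(out) <- NULL
  out
}
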