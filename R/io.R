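#' Read a phantom / study configuration from YAML
#'
#' The YAML file may carry any subset of the sections `phantom`, `grid`,
#' `physics`; omitted fields fall back to the package defaults. Field names
#' match the corresponding constructor arguments.
#'
#' @param path path to a YAML file.
#' @return a [study_config()] built from the file.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec <- do.call(phantom_spec, cfg$phantom %||% list())
  grid <- do.call(voxel_grid, cfg$grid %||% list())
  physics <- do.call(physics_model, cfg$physics %||% list())
  args <- list(spec = spec, grid = grid, physics = physics)
  if (!is.null(cfg$scfs)) args$scfs <- as.numeric(cfg$scfs)
  if (!is.null(cfg$postfilter)) args$postfilter <- cfg$postfilter
  do.call(study_config, args)
}

#' Write a volume as NIfTI
#'
#' @param vol 3-D numeric array (activity, mu, labels or a reconstruction).
#' @param grid the [voxel_grid()] supplying the voxel size.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(vol, grid, path) {
  if (inherits(vol, "recon_volume")) vol <- vol$values
  img <- RNifti::asNifti(vol, pixdim = rep(grid$voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a volume as raw float32 with a JSON sidecar
#'
#' A plain-format alternative to NIfTI: little-endian float32 voxels in
#' Fortran order plus a JSON sidecar describing shape, voxel size and units.
#'
#' @param vol 3-D numeric array.
#' @param grid the [voxel_grid()].
#' @param path output path for the raw data; the sidecar gets `.json`
#'   appended.
#' @param units free-text unit label stored in the sidecar.
#' @return the path, invisibly.
#' @export
write_volume_raw <- function(vol, grid, path, units = "") {
  if (inherits(vol, "recon_volume")) {
    units <- vol$units
    vol <- vol$values
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol), con, size = 4, endian = "little")
  meta <- list(shape = dim(vol), voxel_size_mm = grid$voxel_size,
               origin_mm = grid$origin, dtype = "float32", order = "F",
               units = units)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write grid metrics and effect tables
#'
#' Emits the tidy per-protocol, per-VOI metrics as CSV plus a JSON run
#' manifest (seed, grid, reference, effect table).
#'
#' @param result the list returned by [run_grid()].
#' @param dir output directory (created if needed).
#' @param seed the seed the run used (recorded in the manifest).
#' @param effects optional [summarize_effects()] table to include.
#' @return the directory, invisibly.
#' @export
write_grid_results <- function(result, dir, seed = NA, effects = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(effects))
    write.csv(effects, file.path(dir, "effects.csv"), row.names = FALSE)
  manifest <- list(seed = seed,
                   n_cells = nrow(result$grid),
                   n_failed = result$n_failed,
                   protocols = result$grid$protocol_id,
                   reference = if (!is.null(effects)) attr(effects, "reference") else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
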