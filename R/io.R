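# Raster and study I/O. Grids are unprojected north-up matrices with square
# cells; rasters are stored as single-band 32-bit TIFF. TIFF float samples
# are portable only inside [0, 1], so values are min-max scaled on write and
# restored on read via a JSON sidecar ("<file>.json") that records the
# original range, the cell size and the nodata pattern.

#' Write a grid as a single-band TIFF with a range sidecar
#'
#' @param grid Numeric matrix (`NA` = nodata).
#' @param path Output path (".tif").
#' @param cell_size Cell edge (m), recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, cell_size = 1) {
  grid <- as.matrix(grid)
  finite <- is.finite(grid)
  lo <- if (any(finite)) min(grid[finite]) else 0
  hi <- if (any(finite)) max(grid[finite]) else 1
  span <- if (hi > lo) hi - lo else 1
  scaled <- (grid - lo) / span
  scaled[!finite] <- 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32)
  meta <- list(min = lo, max = hi, cell_size = cell_size,
               nodata_cells = which(!finite))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grid written by [write_raster()]
#'
#' @param path Path to the ".tif" file.
#' @return List with `grid` (matrix) and `cell_size`.
#' @export
read_raster <- function(path) {
  scaled <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  span <- if (meta$max > meta$min) meta$max - meta$min else 1
  grid <- scaled * span + meta$min
  if (length(meta$nodata_cells) > 0) grid[meta$nodata_cells] <- NA
  list(grid = grid, cell_size = meta$cell_size)
}

#' Write a synthetic study to disk
#'
#' Emits, under `out_dir`: per-lake DEM and band rasters (TIFF + sidecars),
#' the lake metadata, food-web samples and dropping transects as CSV, and
#' the planted ground truth as JSON.
#'
#' @param study,truth The two elements returned by [generate_study()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$lakes, file.path(out_dir, "lakes.csv"),
                   row.names = FALSE)
  utils::write.csv(study$samples, file.path(out_dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(study$droppings, file.path(out_dir, "droppings.csv"),
                   row.names = FALSE)
  ras_dir <- file.path(out_dir, "rasters")
  dir.create(ras_dir, showWarnings = FALSE)
  cs <- study$config$cell_size
  for (id in names(study$dems)) {
    d <- study$dems[[id]]
    write_raster(d$dem, file.path(ras_dir, paste0("dem_", id, ".tif")), cs)
    write_raster(d$lake_mask + 0,
                 file.path(ras_dir, paste0("lake_", id, ".tif")), cs)
    for (m in names(study$scenes[[id]])) {
      sc <- study$scenes[[id]][[m]]
      for (band in c("green", "red", "nir", "swir")) {
        write_raster(sc[[band]],
                     file.path(ras_dir,
                               paste0(band, "_", id, "_", m, ".tif")), cs)
      }
    }
  }
  gt <- list(fsc = truth$fsc, veg_ndvi = truth$veg_ndvi,
             droppings = truth$droppings, diets = truth$diets,
             true_tp = truth$true_tp, slopes = truth$slopes)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
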