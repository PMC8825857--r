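# NDVI / NDSI and catchment summaries. Band grids are plain matrices of
# surface reflectance in [0, 1]; NA marks nodata. All grids for one scene
# must be co-registered (same shape, same cell size).

.check_bands <- function(a, b) {
  if (!all(dim(as.matrix(a)) == dim(as.matrix(b)))) {
    stop("band grids are not co-registered (shape mismatch)")
  }
}

.norm_diff <- function(p, q) {
  .check_bands(p, q)
  p <- as.matrix(p); q <- as.matrix(q)
  den <- p + q
  out <- (p - q) / den
  out[!is.finite(out)] <- NA
  out
}

#' Normalised Difference Vegetation Index
#'
#' NDVI = (NIR - Red) / (NIR + Red), a proxy for vegetation productivity.
#' Cells where NIR + Red = 0 (or either band is nodata) return `NA`.
#'
#' @param nir,red Co-registered reflectance matrices in [0, 1].
#' @return Index matrix in [-1, 1] (NA where undefined).
#' @export
ndvi <- function(nir, red) .norm_diff(nir, red)

#' Normalised Difference Snow Index
#'
#' NDSI = (Green - SWIR) / (Green + SWIR), which separates snow (bright in
#' the visible, dark in shortwave infrared) from bare soil and vegetation.
#'
#' @param green,swir Co-registered reflectance matrices in [0, 1].
#' @return Index matrix in [-1, 1] (NA where undefined).
#' @export
ndsi <- function(green, swir) .norm_diff(green, swir)

#' Classify snow cells with a two-node decision tree
#'
#' A cell is snow iff NDSI >= `ndsi_min` AND Red reflectance >= `red_min`.
#' The Red test rejects cells that are bright in NDSI but dark in the
#' visible (water, shadow). Default thresholds are NDSI >= 0.40 (standard
#' Landsat snow mapping) and Red >= 0.20.
#'
#' @param ndsi_grid NDSI matrix from [ndsi()].
#' @param red Red reflectance matrix.
#' @param thresholds Numeric `c(ndsi_min, red_min)`; ndsi_min in [-1, 1],
#'   red_min in [0, 1].
#' @return Logical matrix; `FALSE` at nodata cells.
#' @export
classify_snow <- function(ndsi_grid, red, thresholds = c(0.40, 0.20)) {
  .check_bands(ndsi_grid, red)
  if (thresholds[1] < -1 || thresholds[1] > 1 ||
      thresholds[2] < 0 || thresholds[2] > 1) {
    stop("thresholds out of range: ndsi_min in [-1,1], red_min in [0,1]")
  }
  snow <- ndsi_grid >= thresholds[1] & red >= thresholds[2]
  snow[is.na(snow)] <- FALSE
  snow
}

#' Fraction of snow coverage in a catchment
#'
#' FSC = snow cells within the catchment / catchment land cells. Lake cells
#' are excluded from the denominator (and numerator) when a lake mask is
#' given.
#'
#' @param snow_mask Logical snow matrix.
#' @param catchment_mask Logical catchment matrix (same shape).
#' @param lake_mask Optional logical lake matrix excluded from the land area.
#' @return Fraction in [0, 1].
#' @export
snow_cover_fraction <- function(snow_mask, catchment_mask, lake_mask = NULL) {
  .check_bands(snow_mask, catchment_mask)
  land <- catchment_mask
  if (!is.null(lake_mask)) {
    .check_bands(catchment_mask, lake_mask)
    land <- land & !lake_mask
  }
  n_land <- sum(land)
  if (n_land == 0) stop("catchment has no land cells")
  sum(snow_mask & land) / n_land
}

#' Buffer zone around a lake
#'
#' Marks the cells whose centre lies within `distance_m` of the nearest
#' lake-cell centre, excluding the lake cells themselves. Distances are
#' Euclidean, centre to centre, so the result is resolution-independent up
#' to the cell size.
#'
#' @param lake_mask Logical matrix of lake cells.
#' @param distance_m Buffer distance in metres, > 0 (the study uses 100 m).
#' @param cell_size Cell edge length in metres.
#' @return Logical matrix: the buffer ring (never overlapping the lake).
#' @export
lake_buffer <- function(lake_mask, distance_m = 100, cell_size = 1) {
  lake_mask <- as.matrix(lake_mask)
  if (distance_m <= 0) stop("distance_m must be positive")
  if (!any(lake_mask)) stop("empty lake mask")
  nr <- nrow(lake_mask); nc <- ncol(lake_mask)
  lk <- which(lake_mask, arr.ind = TRUE)
  # squared distance from every cell centre to the nearest lake-cell centre
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  lim2 <- (distance_m / cell_size)^2
  d2min <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(lk))) {
    d2 <- (rows - lk[i, 1])^2 + (cols - lk[i, 2])^2
    d2min <- pmin(d2min, d2)
  }
  buf <- d2min <= lim2 & !lake_mask
  buf
}

#' Per-catchment NDVI summaries across the summer scenes
#'
#' Produces the summaries used throughout the analysis:
#' * `mean_ndvi` - mean NDVI over catchment land cells, averaged over the
#'   available June-August scenes ("mean NDVI in summer");
#' * `near_lake_ndvi` - mean over the 100-m buffer in August;
#' * `catchment_ndvi` - mean over the catchment minus the buffer in August;
#' * `delta_ndvi` - near-lake minus catchment NDVI (August);
#' * `seasonal_change` - August minus June near-lake NDVI.
#'
#' Lake cells never contribute to any mean.
#'
#' @param ndvi_by_month Named list of NDVI matrices; names are month labels.
#'   Must contain `"Jun"` and `"Aug"`; `"Jul"` is used when present.
#' @param catchment_mask,lake_mask Logical matrices.
#' @param buffer Logical buffer matrix from [lake_buffer()].
#' @return List with the five summaries.
#' @export
ndvi_summaries <- function(ndvi_by_month, catchment_mask, lake_mask, buffer) {
  for (m in c("Jun", "Aug")) {
    if (is.null(ndvi_by_month[[m]])) {
      stop("missing required month: ", m)
    }
  }
  land <- catchment_mask & !lake_mask
  ring <- buffer & land
  outer <- land & !ring
  mean_in <- function(grid, mask) mean(grid[mask], na.rm = TRUE)

  summer <- intersect(c("Jun", "Jul", "Aug"), names(ndvi_by_month))
  mean_ndvi <- mean(vapply(summer, function(m) {
    mean_in(ndvi_by_month[[m]], land)
  }, numeric(1)))

  aug <- ndvi_by_month[["Aug"]]
  jun <- ndvi_by_month[["Jun"]]
  near_lake <- mean_in(aug, ring)
  catchment <- mean_in(aug, outer)
  list(mean_ndvi = mean_ndvi,
       near_lake_ndvi = near_lake,
       catchment_ndvi = catchment,
       delta_ndvi = near_lake - catchment,
       seasonal_change = near_lake - mean_in(jun, ring))
}
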