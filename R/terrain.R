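# D8 terrain analysis on north-up square-cell grids.
# Grid convention: matrices with row 1 = north, 0-based cell ids are not
# used; cells are addressed (row, col), 1-based, cell-centre registration.
# Neighbour order everywhere: E, SE, S, SW, W, NW, N, NE (deterministic
# tie-break order for equal drops).

.d8_dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
.d8_dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

# shift a matrix so that entry (r, c) holds m[r + dr, c + dc]; outside -> fill
.shift_mat <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Fill DEM depressions
#'
#' Raises every interior pit to its lowest pour point so each cell has a
#' non-ascending path to the grid edge (or to a nodata cell, which is
#' treated as free drainage). Uses the iterative least-upper-bound
#' (Planchon-Darboux) fill, whose fixed point is the unique minimal filled
#' surface; the result is order-independent and idempotent.
#'
#' @param dem Numeric elevation matrix; `NA` marks nodata.
#' @return Filled elevation matrix, >= `dem` everywhere, same `NA` pattern.
#' @export
fill_depressions <- function(dem) {
  dem <- as.matrix(dem)
  if (all(is.na(dem))) stop("all-nodata DEM cannot be filled")
  nr <- nrow(dem); nc <- ncol(dem)
  valid <- !is.na(dem)
  edge <- matrix(FALSE, nr, nc)
  edge[1, ] <- TRUE; edge[nr, ] <- TRUE; edge[, 1] <- TRUE; edge[, nc] <- TRUE
  # cells adjacent to nodata also drain freely
  near_na <- matrix(FALSE, nr, nc)
  for (k in 1:8) {
    nb_valid <- .shift_mat(valid + 0, .d8_dr[k], .d8_dc[k], fill = 1)
    near_na <- near_na | (nb_valid == 0)
  }
  drains <- (edge | near_na) & valid

  # nodata is carried as +Inf internally so pmin/pmax stay NA-free
  z <- dem
  z[!valid] <- Inf
  w <- matrix(Inf, nr, nc)
  w[drains] <- dem[drains]
  repeat {
    nb_min <- matrix(Inf, nr, nc)
    for (k in 1:8) {
      nb <- .shift_mat(w, .d8_dr[k], .d8_dc[k], fill = -Inf)
      nb_min <- pmin(nb_min, nb)
    }
    cand <- pmax(z, nb_min)
    w_new <- pmin(w, cand)
    w_new[drains] <- dem[drains]
    if (identical(w_new, w)) break
    w <- w_new
  }
  w_new[!valid] <- NA
  w_new
}

#' D8 flow directions and flow accumulation
#'
#' Each cell drains to its steepest-descent neighbour (drop divided by
#' centre distance, diagonal distance sqrt(2) * cell size). Direction codes
#' are 1..8 in the order E, SE, S, SW, W, NW, N, NE; 0 marks an outlet
#' (no lower in-grid neighbour on the grid edge or beside nodata); `NA`
#' marks nodata. Ties among equal drops break to the first neighbour in the
#' fixed order. Flats left by depression filling are resolved by a
#' deterministic breadth-first gradient away from the flat's pour cells, so
#' every flat cell drains towards the flat's exit.
#'
#' Accumulation counts contributing cells (each cell counts itself):
#' acc(c) = 1 + sum of acc over neighbours draining into c, computed by a
#' topological pass over the drainage forest.
#'
#' @param dem Depression-filled elevation matrix (`NA` = nodata).
#' @param cell_size Cell edge length in metres (default 1).
#' @return List of class `arclakes_flow`: `direction` (integer matrix),
#'   `accumulation` (numeric matrix), `cell_size`.
#' @export
d8_flow_directions <- function(dem, cell_size = 1) {
  dem <- as.matrix(dem)
  nr <- nrow(dem); nc <- ncol(dem)
  valid <- !is.na(dem)
  if (!any(valid)) stop("all-nodata DEM")
  dist <- ifelse(.d8_dr != 0 & .d8_dc != 0, sqrt(2) * cell_size, cell_size)

  grad <- array(-Inf, dim = c(nr, nc, 8))
  nb_is_na <- matrix(FALSE, nr, nc)
  nb_equal <- array(FALSE, dim = c(nr, nc, 8))
  for (k in 1:8) {
    nb <- .shift_mat(dem, .d8_dr[k], .d8_dc[k], fill = NA_real_)
    off_or_na <- is.na(nb)
    nb_is_na <- nb_is_na | off_or_na
    g <- (dem - nb) / dist[k]
    g[off_or_na] <- -Inf
    grad[, , k] <- g
    nb_equal[, , k] <- !off_or_na & nb == dem
  }

  gmat <- matrix(grad, nrow = nr * nc, ncol = 8)
  best_k <- max.col(gmat, ties.method = "first")
  best_g <- gmat[cbind(seq_len(nr * nc), best_k)]

  direction <- matrix(NA_integer_, nr, nc)
  downhill <- valid & matrix(best_g > 0, nr, nc)
  direction[downhill] <- best_k[as.vector(downhill)]
  # cells with no lower neighbour draining off-grid / into nodata -> outlet
  outlet <- valid & !downhill & nb_is_na
  direction[outlet] <- 0L

  # resolve flats: BFS from resolved cells across equal-elevation neighbours
  unresolved <- valid & !downhill & !outlet
  if (any(unresolved)) {
    eqmat <- matrix(nb_equal, nrow = nr * nc, ncol = 8)
    # seed: unresolved cells with a resolved equal-elevation neighbour
    queue <- integer(0)
    resolved <- !unresolved & valid
    res_vec <- as.vector(resolved)
    unres_vec <- as.vector(unresolved)
    dir_vec <- as.vector(direction)
    nb_index <- matrix(NA_integer_, nrow = nr * nc, ncol = 8)
    for (k in 1:8) {
      rr <- ((seq_len(nr * nc) - 1L) %% nr) + 1L + .d8_dr[k]
      cc <- ((seq_len(nr * nc) - 1L) %/% nr) + 1L + .d8_dc[k]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      idx <- rep(NA_integer_, nr * nc)
      idx[ok] <- (cc[ok] - 1L) * nr + rr[ok]
      nb_index[, k] <- idx
    }
    # iterative waves: assign unresolved cells pointing at a resolved
    # equal-elevation neighbour (or any resolved neighbour reached by the
    # flat gradient); repeat until fixed point
    repeat {
      assigned_any <- FALSE
      for (k in 1:8) {
        cand <- which(unres_vec & eqmat[, k])
        if (length(cand) == 0) next
        nbi <- nb_index[cand, k]
        ok <- !is.na(nbi) & res_vec[nbi]
        hit <- cand[ok]
        if (length(hit) > 0) {
          dir_vec[hit] <- k
          unres_vec[hit] <- FALSE
          # do not mark resolved yet: within a wave, keep determinism
          assigned_any <- TRUE
          queue <- c(queue, hit)
        }
      }
      res_vec[queue] <- TRUE
      queue <- integer(0)
      if (!assigned_any) break
    }
    if (any(unres_vec)) {
      stop("internal error: unresolved flat cells remain (is the DEM filled?)")
    }
    direction <- matrix(dir_vec, nr, nc)
  }

  acc <- .flow_accumulation(direction, nr, nc)
  structure(list(direction = direction, accumulation = acc,
                 cell_size = cell_size),
            class = "arclakes_flow")
}

# index of the cell each cell drains to (NA for outlet / nodata)
.downstream_index <- function(direction, nr, nc) {
  idx <- seq_len(nr * nc)
  dirv <- as.vector(direction)
  out <- rep(NA_integer_, nr * nc)
  has <- !is.na(dirv) & dirv > 0
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  rr <- r[has] + .d8_dr[dirv[has]]
  cc <- c[has] + .d8_dc[dirv[has]]
  bad <- rr < 1 | rr > nr | cc < 1 | cc > nc
  if (any(bad)) stop("internal error: direction points off-grid")
  out[has] <- (cc - 1L) * nr + rr
  out
}

.flow_accumulation <- function(direction, nr, nc) {
  ds <- .downstream_index(direction, nr, nc)
  defined <- !is.na(as.vector(direction))
  n <- nr * nc
  indeg <- tabulate(ds[defined & !is.na(ds)], nbins = n)
  acc <- rep(NA_real_, n)
  acc[defined] <- 1
  queue <- which(defined & indeg == 0)
  head <- 1L
  queue <- c(queue, integer(0))
  while (head <= length(queue)) {
    i <- queue[head]; head <- head + 1L
    d <- ds[i]
    if (!is.na(d)) {
      acc[d] <- acc[d] + acc[i]
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) queue <- c(queue, d)
    }
  }
  if (any(indeg[defined] > 0)) {
    stop("internal error: cycle detected in flow directions")
  }
  matrix(acc, nr, nc)
}

#' Delineate the catchment draining into a lake
#'
#' The catchment is the set of cells whose D8 flow path reaches the lake
#' mask, plus the lake cells themselves. Computed by a reverse breadth-first
#' traversal of the drainage forest.
#'
#' @param flow An `arclakes_flow` object from [d8_flow_directions()].
#' @param lake_mask Logical matrix marking lake cells (same shape).
#' @param lake_id Optional identifier carried through to the result.
#' @return List of class `arclakes_catchment`: `mask` (logical matrix),
#'   `lake_mask`, `lake_id`, `area_m2`, `lake_area_m2`, `cell_size`.
#' @export
delineate_catchment <- function(flow, lake_mask, lake_id = NA) {
  stopifnot(inherits(flow, "arclakes_flow"))
  lake_mask <- as.matrix(lake_mask)
  nr <- nrow(flow$direction); nc <- ncol(flow$direction)
  if (!all(dim(lake_mask) == c(nr, nc))) stop("lake mask shape mismatch")
  if (!any(lake_mask)) stop("empty lake mask")
  ds <- .downstream_index(flow$direction, nr, nc)
  n <- nr * nc
  inflows <- split(which(!is.na(ds)), ds[!is.na(ds)])
  member <- as.vector(lake_mask)
  queue <- which(member)
  head <- 1L
  while (head <= length(queue)) {
    i <- queue[head]; head <- head + 1L
    ups <- inflows[[as.character(i)]]
    if (!is.null(ups)) {
      new <- ups[!member[ups]]
      if (length(new) > 0) {
        member[new] <- TRUE
        queue <- c(queue, new)
      }
    }
  }
  mask <- matrix(member, nr, nc)
  mask[is.na(flow$direction)] <- FALSE
  mask <- mask | lake_mask
  cs <- flow$cell_size
  structure(list(mask = mask, lake_mask = lake_mask, lake_id = lake_id,
                 area_m2 = sum(mask) * cs^2,
                 lake_area_m2 = sum(lake_mask) * cs^2,
                 cell_size = cs),
            class = "arclakes_catchment")
}

#' Lake-to-catchment area ratio
#'
#' Lake surface area divided by catchment area (the catchment includes the
#' lake). Small values mean a large relative terrestrial drainage; in the
#' study's terminology, the lower this ratio the higher the lake's
#' "openness" to terrestrial inputs. The ratio itself is always what is
#' stored and reported, labelled `lc_ratio`.
#'
#' @param lake_area_m2 Lake surface area (m^2), > 0.
#' @param catchment_area_m2 Catchment area (m^2), >= lake area.
#' @return Dimensionless ratio in (0, 1].
#' @export
openness_ratio <- function(lake_area_m2, catchment_area_m2) {
  if (any(lake_area_m2 <= 0) || any(catchment_area_m2 <= 0)) {
    stop("areas must be positive")
  }
  if (any(lake_area_m2 > catchment_area_m2)) {
    stop("lake area cannot exceed catchment area")
  }
  lake_area_m2 / catchment_area_m2
}

#' Export the stream network as an edge list
#'
#' Writes one row per drained cell: linear `from_cell` and `to_cell` indices
#' (column-major, 1-based) and the flow accumulation at the source cell,
#' optionally keeping only cells above an accumulation threshold.
#'
#' @param flow An `arclakes_flow` object.
#' @param path Output CSV path.
#' @param min_accumulation Keep edges with accumulation >= this (default 1).
#' @return The edge-list data frame, invisibly.
#' @export
write_stream_network <- function(flow, path, min_accumulation = 1) {
  nr <- nrow(flow$direction); nc <- ncol(flow$direction)
  ds <- .downstream_index(flow$direction, nr, nc)
  accv <- as.vector(flow$accumulation)
  keep <- !is.na(ds) & accv >= min_accumulation
  edges <- data.frame(from_cell = which(keep), to_cell = ds[keep],
                      accumulation = accv[keep])
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(edges)
}
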