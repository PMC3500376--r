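# Least-cost connectivity: multi-source cost-distance accumulation over an
# 8-connected grid graph (edge weight = mean of endpoint costs times
# center-to-center distance), corridor surfaces as the sum of the
# cost-distances from source and destination patches, least-cost path
# backtracking, and percentile corridor slicing.

#' Accumulated cost distance from a source cell set
#'
#' Multi-source Dijkstra on the 8-connected grid graph; edge weight between
#' neighbours a, b is `mean(cost_a, cost_b) * d` with `d` the cell size
#' (orthogonal) or `cellsize * sqrt(2)` (diagonal). Source cells score 0;
#' unreachable cells score `Inf`.
#'
#' @param cost continuous [raster_layer()] of strictly positive costs.
#' @param sources cell set: two-column (row, col) matrix or linear indices.
#' @return continuous [raster_layer()] of accumulated costs.
#' @export
cost_distance <- function(cost, sources) {
  check_costs(cost)
  src <- cells_to_linear(cost$spec, sources)
  res <- grid_dijkstra(cost$values, src, cost$spec$cellsize)
  raster_layer(res$dist, cost$spec, "continuous")
}

check_costs <- function(cost) {
  v <- valid_values(cost)
  if (any(v <= 0)) stop("costs must be strictly positive (>= r_min)")
  invisible(TRUE)
}

cells_to_linear <- function(spec, cells) {
  m <- as_cell_matrix(spec, cells)
  as.integer(m[, 1] + (m[, 2] - 1L) * spec$nrows)
}

#' Corridor-cost surface between two patches
#'
#' Cell-wise sum of the cost-distance from the source patch and from the
#' destination patch(es); its minimum equals the patch-to-patch least-cost
#' path cost, attained along every optimal path.
#'
#' @param cd_source,cd_dest [raster_layer()]s from [cost_distance()] on the
#'   same cost layer.
#' @return continuous [raster_layer()].
#' @export
corridor_surface <- function(cd_source, cd_dest) {
  if (!same_spec(cd_source$spec, cd_dest$spec)) stop("grid mismatch")
  raster_layer(cd_source$values + cd_dest$values, cd_source$spec,
               "continuous")
}

#' Least-cost path between cell sets
#'
#' Runs multi-source Dijkstra from `source_cells` and backtracks from the
#' cheapest destination cell. Equal-cost ties resolve toward the smallest
#' (row, col) predecessor, so the returned path is deterministic.
#'
#' @param cost continuous [raster_layer()] of strictly positive costs.
#' @param source_cells,dest_cells cell sets ((row, col) matrix or linear
#'   indices).
#' @return list with `path` (two-column (row, col) matrix, source to
#'   destination) and `cost` (total accumulated cost).
#' @export
least_cost_path <- function(cost, source_cells, dest_cells) {
  check_costs(cost)
  sp <- cost$spec
  src <- cells_to_linear(sp, source_cells)
  dst <- cells_to_linear(sp, dest_cells)
  res <- grid_dijkstra(cost$values, src, sp$cellsize)
  dvec <- res$dist
  dd <- dvec[dst]
  if (all(!is.finite(dd))) stop("destination unreachable from source")
  end <- dst[which.min(dd)]
  path <- integer(0)
  cur <- end
  while (cur != 0) {
    path <- c(cur, path)
    if (cur %in% src) break
    cur <- res$pred[cur]
  }
  if (!(path[1] %in% src)) stop("backtracking failed to reach a source cell")
  m <- cbind(row = (path - 1L) %% sp$nrows + 1L,
             col = (path - 1L) %/% sp$nrows + 1L)
  list(path = m, cost = min(dd))
}

#' Slice a corridor mask from a corridor-cost surface
#'
#' `basis = "area_percentile"` (default) keeps the cells at or below the
#' p-th percentile of valid-cell values: the minimal superset of the
#' lowest-cost `p`% of cells (ties included). `basis = "value_range"` keeps
#' cells with `surface <= min + (p/100) (max - min)`. Slices nest in `p`
#' under either basis.
#'
#' @param surface continuous [raster_layer()] (lower = more traversable).
#' @param p threshold percentage in (0, 100].
#' @param basis `"area_percentile"` or `"value_range"`.
#' @param provenance optional named list stored on the mask (season, hsm,
#'   method, threshold).
#' @return binary [raster_layer()] with attribute `provenance`.
#' @export
slice_corridor <- function(surface, p, basis = c("area_percentile", "value_range"),
                           provenance = NULL) {
  basis <- match.arg(basis)
  stopifnot(p > 0, p <= 100)
  v <- surface$values
  vv <- v[!is.na(v) & is.finite(v)]
  if (length(unique(vv)) == 1) stop("constant corridor surface")
  thr <- if (basis == "area_percentile") {
    sort(vv)[ceiling(p / 100 * length(vv))]
  } else {
    min(vv) + p / 100 * (max(vv) - min(vv))
  }
  mask <- ifelse(!is.na(v) & is.finite(v) & v <= thr, 1, 0)
  mask[is.na(v)] <- NA_real_
  out <- raster_layer(mask, surface$spec, "binary")
  attr(out, "provenance") <- c(provenance,
                               list(threshold_pct = p, basis = basis,
                                    threshold_value = thr))
  out
}

#' Build a least-cost corridor for a patch pair
#'
#' Convenience wrapper: cost-distance from the source patch, cost-distance
#' from the destination patch set (their union acts as one multi-source
#' set, equivalent to the cell-wise minimum over per-destination
#' surfaces), summed.
#'
#' @param cost continuous cost [raster_layer()].
#' @param source_cells,dest_cells cell sets.
#' @return continuous corridor-cost [raster_layer()].
#' @export
lcm_corridor_surface <- function(cost, source_cells, dest_cells) {
  corridor_surface(cost_distance(cost, source_cells),
                   cost_distance(cost, dest_cells))
}
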