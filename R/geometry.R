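# Light vector-geometry layer: polyline sets, point-segment distance,
# line rasterization. Deliberately minimal -- no projections, no topology
# beyond what fence modelling needs.

#' Polyline set
#'
#' @param lines list of polylines; each polyline is a list with `coords`
#'   (two-column matrix of map coordinates, >= 2 vertices) and an optional
#'   `attrs` list.
#' @return object of class `line_set`.
#' @export
line_set <- function(lines = list()) {
  for (ln in lines) {
    if (!is.matrix(ln$coords) || ncol(ln$coords) != 2 || nrow(ln$coords) < 2)
      stop("each polyline needs a coords matrix with >= 2 vertices")
    if (all(ln$coords[1, ] == ln$coords[nrow(ln$coords), ]) &&
        nrow(ln$coords) == 2)
      stop("degenerate polyline (zero length)")
  }
  structure(list(lines = lines), class = "line_set")
}

#' @exportS3Method base::print
print.line_set <- function(x, ...) {
  cat(sprintf("<line_set: %d polylines, %d segments>\n",
              length(x$lines), nrow(segments_of(x))))
}

#' Number of polylines in a line set
#' @param x a [line_set()].
#' @return integer count.
#' @export
n_lines <- function(x) length(x$lines)

# Flatten a line_set into a segment table (x1, y1, x2, y2, line_id)
segments_of <- function(ls) {
  segs <- lapply(seq_along(ls$lines), function(i) {
    co <- ls$lines[[i]]$coords
    n <- nrow(co)
    if (n < 2) return(NULL)
    cbind(x1 = co[-n, 1], y1 = co[-n, 2], x2 = co[-1, 1], y2 = co[-1, 2],
          line_id = i)
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) out <- matrix(numeric(0), ncol = 5,
                                  dimnames = list(NULL, c("x1", "y1", "x2", "y2", "line_id")))
  out
}

# Distance from points (px, py) to one segment
point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Minimum distance from points to any polyline of a line set
#' @param points two-column matrix of (x, y) map coordinates.
#' @param lines a [line_set()].
#' @return numeric vector of distances in meters (`Inf` if the set is empty).
#' @export
dist_to_lines <- function(points, lines) {
  segs <- segments_of(lines)
  d <- rep(Inf, nrow(points))
  for (k in seq_len(nrow(segs))) {
    d <- pmin(d, point_segment_dist(points[, 1], points[, 2],
                                    segs[k, 1], segs[k, 2],
                                    segs[k, 3], segs[k, 4]))
  }
  d
}

#' Rasterize a line set onto a grid
#'
#' Marks every cell whose center lies within `radius` (default half a cell)
#' of any polyline.
#'
#' @param spec a [grid_spec()].
#' @param lines a [line_set()].
#' @param radius capture radius in meters.
#' @return binary [raster_layer()].
#' @export
rasterize_lines <- function(spec, lines, radius = spec$cellsize / 2) {
  out <- matrix(0, spec$nrows, spec$ncols)
  segs <- segments_of(lines)
  cs <- spec$cellsize
  for (k in seq_len(nrow(segs))) {
    xr <- range(segs[k, c(1, 3)]); yr <- range(segs[k, c(2, 4)])
    c0 <- max(1L, floor((xr[1] - radius - spec$origin_x) / cs) + 1L)
    c1 <- min(spec$ncols, ceiling((xr[2] + radius - spec$origin_x) / cs))
    r0 <- max(1L, floor((spec$origin_y - yr[2] - radius) / cs) + 1L)
    r1 <- min(spec$nrows, ceiling((spec$origin_y - yr[1] + radius) / cs))
    if (c1 < c0 || r1 < r0) next
    rows <- r0:r1; cols <- c0:c1
    grid <- expand.grid(row = rows, col = cols)
    ctr <- cell_centers(spec, grid$row, grid$col)
    d <- point_segment_dist(ctr[, 1], ctr[, 2], segs[k, 1], segs[k, 2],
                            segs[k, 3], segs[k, 4])
    hit <- grid[d <= radius, , drop = FALSE]
    out[cbind(hit$row, hit$col)] <- 1
  }
  raster_layer(out, spec, "binary")
}

#' Write a line set as GeoJSON-style text
#' @param lines a [line_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lines_geojson <- function(lines, path) {
  features <- lapply(lines$lines, function(ln) {
    list(type = "Feature",
         properties = if (length(ln$attrs)) ln$attrs else structure(list(), names = character()),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(ln$coords, 1, function(p) as.list(unname(p)),
                                                    simplify = FALSE))))
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a line set written by [write_lines_geojson()]
#' @param path input path.
#' @return a [line_set()].
#' @export
read_lines_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  lines <- lapply(obj$features, function(f) {
    co <- do.call(rbind, lapply(f$geometry$coordinates,
                                function(p) c(p[[1]], p[[2]])))
    list(coords = co, attrs = f$properties)
  })
  line_set(lines)
}
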