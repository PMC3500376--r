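#' @useDynLib corridorscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Grid specification
#'
#' Describes the regular, square-celled planar grid every raster in an
#' analysis shares: dimensions, cell size in meters, and the map coordinate
#' of the outer corner of the top-left cell. Row 1 is the map top; the
#' center of cell (r, c) lies at `(origin_x + (c - 0.5) * cellsize,
#' origin_y - (r - 0.5) * cellsize)`.
#'
#' @param nrows,ncols positive integers.
#' @param cellsize cell edge length in meters (> 0; cells are square).
#' @param origin_x,origin_y map coordinates (m) of the top-left outer corner.
#' @param nodata sentinel value used on disk for missing cells.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrows, ncols, cellsize, origin_x = 0,
                      origin_y = nrows * cellsize, nodata = -9999) {
  stopifnot(nrows >= 1, ncols >= 1, cellsize > 0)
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 cellsize = cellsize, origin_x = origin_x,
                 origin_y = origin_y, nodata = nodata),
            class = "grid_spec")
}

#' @exportS3Method base::format
format.grid_spec <- function(x, ...) {
  sprintf("<grid_spec %d x %d @ %g m, origin (%g, %g)>",
          x$nrows, x$ncols, x$cellsize, x$origin_x, x$origin_y)
}

#' @exportS3Method base::print
print.grid_spec <- function(x, ...) cat(format(x), "\n")

same_spec <- function(a, b, tol = 1e-9) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    abs(a$cellsize - b$cellsize) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

#' Raster layer
#'
#' A single grid of values tied to a [grid_spec()]. Missing cells are `NA`
#' in memory; the nodata sentinel appears only on disk. `kind` governs which
#' operations are legal: `"categorical"` layers hold integer codes,
#' `"binary"` layers hold 0/1.
#'
#' @param values numeric matrix, `nrows x ncols` of the spec (row 1 = map top).
#' @param spec a [grid_spec()].
#' @param kind one of `"continuous"`, `"categorical"`, `"binary"`.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, spec, kind = "continuous") {
  kind <- match.arg(kind, c("continuous", "categorical", "binary"))
  values <- as.matrix(values)
  if (nrow(values) != spec$nrows || ncol(values) != spec$ncols)
    stop("values dimensions do not match grid_spec")
  if (kind == "categorical" &&
      any(values[!is.na(values)] != round(values[!is.na(values)])))
    stop("categorical layer must hold integer codes")
  if (kind == "binary" && !all(values[!is.na(values)] %in% c(0, 1)))
    stop("binary layer must hold 0/1")
  structure(list(values = values, spec = spec, kind = kind),
            class = "raster_layer")
}

#' @exportS3Method base::print
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer %s %s; %d valid cells; range [%g, %g]>\n",
              x$kind, format(x$spec), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
}

#' Valid-cell mask of a raster layer
#' @param layer a [raster_layer()].
#' @return logical matrix, `TRUE` where the cell holds data.
#' @export
valid_mask <- function(layer) !is.na(layer$values)

#' Values of the valid cells
#' @param layer a [raster_layer()].
#' @return numeric vector of non-missing cell values (column-major order).
#' @export
valid_values <- function(layer) layer$values[!is.na(layer$values)]

#' Cell center coordinates
#'
#' @param spec a [grid_spec()].
#' @param rows,cols 1-based row/column indices (recycled together).
#' @return two-column matrix of map coordinates (x, y) in meters.
#' @export
cell_centers <- function(spec, rows, cols) {
  cbind(x = spec$origin_x + (cols - 0.5) * spec$cellsize,
        y = spec$origin_y - (rows - 0.5) * spec$cellsize)
}

#' Map coordinates to cell indices
#'
#' Points on a cell's right/bottom edge belong to the next cell
#' (half-open cell extents); points outside the grid return `NA`.
#'
#' @param spec a [grid_spec()].
#' @param x,y map coordinates in meters.
#' @return two-column integer matrix (row, col), `NA` outside the extent.
#' @export
coords_to_cell <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cellsize) + 1L
  row <- floor((spec$origin_y - y) / spec$cellsize) + 1L
  bad <- row < 1L | row > spec$nrows | col < 1L | col > spec$ncols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Euclidean distance to the nearest feature cell
#'
#' Each cell receives the Euclidean distance in meters from its center to the
#' center of the nearest feature cell (feature cells score 0). Used to build
#' the distance-to-water / -roads / -wells covariates.
#'
#' @param spec a [grid_spec()].
#' @param feature_cells two-column matrix of (row, col) indices, or a vector
#'   of column-major linear cell indices.
#' @return continuous [raster_layer()] of distances in meters.
#' @export
distance_to_features <- function(spec, feature_cells) {
  idx <- as_cell_matrix(spec, feature_cells)
  if (nrow(idx) == 0) stop("feature set is empty")
  feat <- matrix(FALSE, spec$nrows, spec$ncols)
  feat[cbind(idx[, 1], idx[, 2])] <- TRUE
  d2 <- edt_squared(feat)
  raster_layer(sqrt(d2) * spec$cellsize, spec, "continuous")
}

as_cell_matrix <- function(spec, cells) {
  if (is.matrix(cells) || is.data.frame(cells)) {
    m <- as.matrix(cells)[, 1:2, drop = FALSE]
  } else {
    cells <- as.integer(cells)
    m <- cbind((cells - 1L) %% spec$nrows + 1L,
               (cells - 1L) %/% spec$nrows + 1L)
  }
  storage.mode(m) <- "integer"
  if (nrow(m) > 0 &&
      (any(m[, 1] < 1 | m[, 1] > spec$nrows) ||
       any(m[, 2] < 1 | m[, 2] > spec$ncols)))
    stop("cell index outside grid")
  m
}

#' Block-aggregate a raster to a coarser resolution
#'
#' Aggregates `factor x factor` blocks (e.g. factor 3 for a 30 m to 90 m
#' resample). Blocks containing at least one valid cell yield a value
#' computed over the valid cells only; all-nodata blocks stay nodata.
#'
#' @param layer a [raster_layer()]; dimensions must be divisible by `factor`.
#' @param factor positive integer aggregation factor.
#' @param method `"mean"` (continuous only) or `"majority"`
#'   (categorical/binary; smallest code wins ties).
#' @return [raster_layer()] on the aggregated grid.
#' @export
resample <- function(layer, factor, method = c("mean", "majority")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (method == "mean" && layer$kind != "continuous")
    stop("mean resampling requires a continuous layer")
  if (method == "majority" && layer$kind == "continuous")
    stop("majority resampling requires a categorical or binary layer")
  sp <- layer$spec
  if (sp$nrows %% factor != 0 || sp$ncols %% factor != 0)
    stop("grid dimensions not divisible by aggregation factor")
  nr2 <- sp$nrows %/% factor; nc2 <- sp$ncols %/% factor
  out <- matrix(NA_real_, nr2, nc2)
  br <- (seq_len(sp$nrows) - 1L) %/% factor + 1L
  bc <- (seq_len(sp$ncols) - 1L) %/% factor + 1L
  for (i in seq_len(nr2)) {
    for (j in seq_len(nc2)) {
      block <- layer$values[br == i, bc == j]
      block <- block[!is.na(block)]
      if (length(block) == 0) next
      out[i, j] <- if (method == "mean") mean(block) else {
        tab <- table(block)
        as.numeric(names(tab)[which.max(tab)])  # ties: smallest code
      }
    }
  }
  spec2 <- grid_spec(nr2, nc2, sp$cellsize * factor, sp$origin_x,
                     sp$origin_y, sp$nodata)
  raster_layer(out, spec2, layer$kind)
}

#' Reclassify a raster
#'
#' Two rule forms:
#' * `list(edges = c(...))` bins a continuous layer into 1-based class codes
#'   with left-closed / right-open intervals on the stated edges
#'   (`[0, e1), [e1, e2), ..., [ek, Inf)`); a value exactly on an edge falls
#'   in the upper class.
#' * `list(map = c("code" = score, ...))` maps categorical codes to numeric
#'   scores; a code absent from the map is an error, never silent nodata.
#'
#' @param layer a [raster_layer()].
#' @param rule rule list as above.
#' @return [raster_layer()] (categorical for `edges`, continuous for `map`);
#'   the valid mask is preserved exactly.
#' @export
reclassify <- function(layer, rule) {
  v <- layer$values
  ok <- !is.na(v)
  if (!is.null(rule$edges)) {
    edges <- rule$edges
    if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must be strictly increasing")
    out <- matrix(NA_real_, nrow(v), ncol(v))
    out[ok] <- findInterval(v[ok], edges) + 1
    return(raster_layer(out, layer$spec, "categorical"))
  }
  if (!is.null(rule$map)) {
    map <- rule$map
    codes <- as.character(v[ok])
    miss <- setdiff(unique(codes), names(map))
    if (length(miss))
      stop("unmapped category code(s): ", paste(miss, collapse = ", "))
    out <- matrix(NA_real_, nrow(v), ncol(v))
    out[ok] <- unname(map[codes])
    return(raster_layer(out, layer$spec, "continuous"))
  }
  stop("rule must contain either $edges or $map")
}

#' Rescale valid cells linearly onto [0, 1]
#' @param layer continuous [raster_layer()] with at least two distinct values.
#' @return continuous [raster_layer()] in `[0, 1]`.
#' @export
rescale01 <- function(layer) {
  v <- valid_values(layer)
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot rescale a constant layer")
  raster_layer((layer$values - rng[1]) / diff(rng), layer$spec, "continuous")
}
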