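# Synthetic prairie landscape generator. Emulates the modelled system: a
# mixed-grass prairie (~56% grassland, ~26% agriculture), a southern
# collaring/source patch and 2-3 northern destination patches >50 km away,
# wells clustered around the source (a gas field), roads and parcel
# boundaries carrying modelled fences, and a known "true" suitability
# surface built with the same weighted-linear-combination scoring the AHP
# engine uses, so recovery tests are well posed.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic landscape parameters
#'
#' Defaults describe a 120 x 120 grid of 900 m cells (a ~108 km square,
#' large enough to hold >50 km seasonal migrations at desk scale), with the
#' study system's land-cover mix: 56% grassland and 26% agriculture, the
#' remainder split across water, development, wetlands and pasture.
#'
#' @param nrows,ncols grid dimensions.
#' @param cellsize cell size in meters.
#' @param landcover_props named proportions for codes water, development,
#'   grassland, wetlands, agriculture, pasture; must sum to 1.
#' @param n_wells number of well points (clustered near the source patch).
#' @param n_water_bodies extra water seed points beyond water land cover.
#' @param n_roads number of roads crossing the extent.
#' @param parcel_rows,parcel_cols parcel tessellation dimensions.
#' @param corlen spatial correlation length of the random fields, in cells.
#' @param source_center,dest_centers patch centers in relative (x, y) extent
#'   coordinates, y increasing northwards; destinations >50 km from source
#'   under the defaults.
#' @param patch_radius_cells habitat patch radius in cells.
#' @param seed integer; fixes the whole stack bit-for-bit.
#' @return object of class `landscape_params`.
#' @export
landscape_params <- function(nrows = 120, ncols = 120, cellsize = 900,
                             landcover_props = c(water = 0.04, development = 0.03,
                                                 grassland = 0.56, wetlands = 0.05,
                                                 agriculture = 0.26, pasture = 0.06),
                             n_wells = 40, n_water_bodies = 8, n_roads = 3,
                             parcel_rows = 6, parcel_cols = 6,
                             corlen = 8,
                             source_center = c(0.50, 0.10),
                             dest_centers = list(c(0.22, 0.88), c(0.50, 0.93),
                                                 c(0.78, 0.87)),
                             patch_radius_cells = 4.5,
                             seed = 1) {
  stopifnot(all(landcover_props >= 0), abs(sum(landcover_props) - 1) < 1e-8,
            n_wells >= 0, n_roads >= 1, parcel_rows >= 1, parcel_cols >= 1)
  if (nrows < 20 || ncols < 20)
    stop("grid too small to place the requested landscape features")
  structure(as.list(environment()), class = "landscape_params")
}

# land cover / terrain category codes (fixed vocabulary)
LANDCOVER_CODES <- c(water = 1, development = 2, grassland = 3,
                     wetlands = 4, agriculture = 5, pasture = 6)
TOPO_CODES <- c(canyon_bottom = 1, flat_gentle = 2, steep = 3, ridge_top = 4)
COVARIATE_ROLES <- c("dist_wells", "dist_water", "dist_roads", "ndvi",
                     "fence", "landcover", "topo_position")

#' Covariate stack
#'
#' The seven predictor layers on one shared grid: distance to wells, water
#' and roads (m), NDVI (0-1), fence presence (binary), land cover and
#' topographic position (categorical).
#'
#' @param layers named list of [raster_layer()], exactly the seven roles.
#' @param season `"spring"` or `"fall"` (NDVI differs by season).
#' @return object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers, season = "spring") {
  if (!setequal(names(layers), COVARIATE_ROLES))
    stop("stack must contain exactly the roles: ",
         paste(COVARIATE_ROLES, collapse = ", "))
  spec <- layers[[1]]$spec
  for (nm in names(layers)) {
    if (!same_spec(layers[[nm]]$spec, spec)) stop("layer ", nm, " misaligned")
  }
  if (layers$fence$kind != "binary") stop("fence layer must be binary")
  if (layers$landcover$kind != "categorical" ||
      layers$topo_position$kind != "categorical")
    stop("landcover and topo_position must be categorical")
  structure(list(layers = layers, spec = spec, season = season),
            class = "covariate_stack")
}

#' @exportS3Method base::print
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack (%s): %s on %s\n", x$season,
              paste(names(x$layers), collapse = ", "), format(x$spec)))
}

# Gaussian-smoothed white-noise field, rescaled to [0, 1]
smooth_field <- function(nr, nc, corlen) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- function(n) {
    m <- stats::dnorm(outer(seq_len(n), seq_len(n), "-") / corlen)
    m / rowSums(m)
  }
  f <- k(nr) %*% w %*% t(k(nc))
  (f - min(f)) / (max(f) - min(f))
}

rel_to_cell <- function(params, rel) {
  # relative (x, y), y northward -> (row, col)
  c(row = round((1 - rel[2]) * (params$nrows - 1)) + 1,
    col = round(rel[1] * (params$ncols - 1)) + 1)
}

#' Generate parcels and roads
#'
#' Parcels form a jittered rectangular tessellation with a random ownership
#' class per parcel; roads are wavy polylines spanning the extent edge to
#' edge. Deterministic under the params seed.
#'
#' @param params a [landscape_params()].
#' @return list with `parcels` (a `parcel_set`: corner array, ownership
#'   matrix, boundary segments with left/right ownership) and `roads`
#'   (a [line_set()]).
#' @export
gen_parcels_and_roads <- function(params) {
  with_seed(params$seed + 101L, {
    sp <- grid_spec(params$nrows, params$ncols, params$cellsize)
    W <- params$ncols * params$cellsize
    H <- params$nrows * params$cellsize
    pr <- params$parcel_rows; pc <- params$parcel_cols
    xs <- seq(0, W, length.out = pc + 1)
    ys <- seq(0, H, length.out = pr + 1)
    jit <- 0.15 * min(W / pc, H / pr)
    cx <- outer(rep(1, pr + 1), xs)
    cy <- outer(ys, rep(1, pc + 1))
    ji <- function(n) stats::runif(n, -jit, jit)
    int_r <- 2:pr; int_c <- 2:pc
    if (pr > 1) cy[int_r, ] <- cy[int_r, ] + matrix(ji((pr - 1) * (pc + 1)), pr - 1)
    if (pc > 1) cx[, int_c] <- cx[, int_c] + matrix(ji((pr + 1) * (pc - 1)), ncol = pc - 1)
    ownership <- matrix(sample(1:3, pr * pc, replace = TRUE), pr, pc)

    boundaries <- list()
    add <- function(p1, p2, own_a, own_b) {
      boundaries[[length(boundaries) + 1]] <<-
        list(coords = rbind(p1, p2), own_a = own_a, own_b = own_b)
    }
    for (i in 1:(pr + 1)) {         # horizontal edges (between row i-1 and i)
      for (j in 1:pc) {
        own_a <- if (i > 1) ownership[i - 1, j] else NA
        own_b <- if (i <= pr) ownership[i, j] else NA
        add(c(cx[i, j], cy[i, j]), c(cx[i, j + 1], cy[i, j + 1]), own_a, own_b)
      }
    }
    for (i in 1:pr) {               # vertical edges (between col j-1 and j)
      for (j in 1:(pc + 1)) {
        own_a <- if (j > 1) ownership[i, j - 1] else NA
        own_b <- if (j <= pc) ownership[i, j] else NA
        add(c(cx[i, j], cy[i, j]), c(cx[i + 1, j], cy[i + 1, j]), own_a, own_b)
      }
    }
    parcels <- structure(list(corner_x = cx, corner_y = cy,
                              ownership = ownership, boundaries = boundaries,
                              extent = c(W, H)),
                         class = "parcel_set")

    roads <- vector("list", params$n_roads)
    for (r in seq_len(params$n_roads)) {
      vertical <- (r %% 2 == 0)
      n_vert <- 9
      if (vertical) {
        x0 <- stats::runif(1, 0.2, 0.8) * W
        ys_r <- seq(0, H, length.out = n_vert)
        xs_r <- pmin(pmax(x0 + smooth_jitter(n_vert, 0.05 * W), 0), W)
        co <- cbind(xs_r, ys_r)
      } else {
        y0 <- stats::runif(1, 0.2, 0.8) * H
        xs_r <- seq(0, W, length.out = n_vert)
        ys_r <- pmin(pmax(y0 + smooth_jitter(n_vert, 0.05 * H), 0), H)
        co <- cbind(xs_r, ys_r)
      }
      roads[[r]] <- list(coords = co, attrs = list(class = "maintained", id = r))
    }
    list(parcels = parcels, roads = line_set(roads))
  })
}

smooth_jitter <- function(n, amp) {
  z <- stats::rnorm(n, 0, amp)
  z <- stats::filter(z, rep(1 / 3, 3), sides = 2)
  z[is.na(z)] <- 0
  as.numeric(z)
}

#' Model fences from parcel boundaries and roads
#'
#' Fences are assumed along internal parcel boundaries separating distinct
#' ownership classes, and along one side of every maintained road (offset by
#' `road_setback`). Coincident lines are dissolved (emitted once).
#'
#' @param parcels a `parcel_set` from [gen_parcels_and_roads()].
#' @param roads a [line_set()] of roads.
#' @param spec a [grid_spec()] for rasterization.
#' @param rules list: `parcel_rule` (`"distinct_ownership"` or `"all"`),
#'   `road_side` (logical), `road_setback` (m).
#' @return list with `lines` (a [line_set()]) and `raster` (binary
#'   [raster_layer()]; cells whose center is within half a cell of a fence).
#' @export
model_fences <- function(parcels, roads, spec,
                         rules = list(parcel_rule = "distinct_ownership",
                                      road_side = TRUE, road_setback = 15)) {
  rules <- utils::modifyList(list(parcel_rule = "distinct_ownership",
                                  road_side = TRUE, road_setback = 15), rules)
  fences <- list()
  if (!is.null(parcels)) {
    for (b in parcels$boundaries) {
      keep <- switch(rules$parcel_rule,
        distinct_ownership = !is.na(b$own_a) && !is.na(b$own_b) &&
                             b$own_a != b$own_b,
        all = TRUE,
        stop("unknown parcel_rule"))
      if (keep)
        fences[[length(fences) + 1]] <- list(coords = b$coords,
                                             attrs = list(source = "parcel"))
    }
  }
  if (isTRUE(rules$road_side) && !is.null(roads)) {
    for (ln in roads$lines) {
      co <- ln$coords
      # offset to one (consistent) side along the unit normal
      dx <- diff(co[, 1]); dy <- diff(co[, 2])
      len <- sqrt(dx^2 + dy^2); len[len == 0] <- 1
      nx <- c(-dy[1] / len[1], -dy / len); ny <- c(dx[1] / len[1], dx / len)
      off <- cbind(co[, 1] + nx * rules$road_setback,
                   co[, 2] + ny * rules$road_setback)
      fences[[length(fences) + 1]] <- list(coords = off,
                                           attrs = list(source = "road"))
    }
  }
  # dissolve: drop polylines whose rounded segment key already appeared
  seen <- character(0)
  keep <- logical(length(fences))
  for (i in seq_along(fences)) {
    co <- round(fences[[i]]$coords, 6)
    key <- paste(apply(co, 1, paste, collapse = ","), collapse = ";")
    rev_key <- paste(rev(apply(co, 1, paste, collapse = ",")), collapse = ";")
    if (!(key %in% seen) && !(rev_key %in% seen)) {
      keep[i] <- TRUE
      seen <- c(seen, key)
    }
  }
  lines <- line_set(fences[keep])
  list(lines = lines, raster = rasterize_lines(spec, lines))
}

#' Ground-truth fence points
#'
#' Samples `n` points along the fence lines (uniform by length), displaces
#' them with isotropic Gaussian noise, and replaces a `contamination`
#' fraction with uniform points across the extent, emulating unmapped
#' fences encountered in the field.
#'
#' @param fences a [line_set()] of modelled fences.
#' @param spec a [grid_spec()] giving the extent for contamination points.
#' @param n number of points (default 1788, the campaign's size).
#' @param displacement_sd GPS noise sd in meters.
#' @param contamination fraction of off-fence points.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `x`, `y`, `on_fence`.
#' @export
gen_fence_truth <- function(fences, spec, n = 1788, displacement_sd = 2,
                            contamination = 0.15, seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    segs <- segments_of(fences)
    if (nrow(segs) == 0) stop("no fence lines to sample")
    lens <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
    n_cont <- round(n * contamination)
    n_on <- n - n_cont
    si <- sample(nrow(segs), n_on, replace = TRUE, prob = lens)
    t <- stats::runif(n_on)
    px <- segs[si, 1] + t * (segs[si, 3] - segs[si, 1]) + stats::rnorm(n_on, 0, displacement_sd)
    py <- segs[si, 2] + t * (segs[si, 4] - segs[si, 2]) + stats::rnorm(n_on, 0, displacement_sd)
    cx <- stats::runif(n_cont, spec$origin_x, spec$origin_x + spec$ncols * spec$cellsize)
    cy <- stats::runif(n_cont, spec$origin_y - spec$nrows * spec$cellsize, spec$origin_y)
    data.frame(id = seq_len(n), x = c(px, cx), y = c(py, cy),
               on_fence = rep(c(TRUE, FALSE), c(n_on, n_cont)))
  })
}

#' Fence model accuracy against ground-truth points
#'
#' Buffers each ground-truth point by `buffer_m` and counts it accurate if
#' any modelled fence line intersects the buffer, i.e. lies within
#' `buffer_m` of the point.
#'
#' @param modeled a [line_set()] of modelled fences.
#' @param truth_points data.frame with `x`, `y` columns.
#' @param buffer_m buffer radius in meters (default 15).
#' @return fraction in `[0, 1]`.
#' @export
fence_accuracy <- function(modeled, truth_points, buffer_m = 15) {
  stopifnot(buffer_m > 0)
  if (nrow(truth_points) == 0) stop("empty ground-truth point set")
  d <- dist_to_lines(as.matrix(truth_points[, c("x", "y")]), modeled)
  mean(d <= buffer_m)
}
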