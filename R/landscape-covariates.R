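# Covariate stack generation and the ground-truth suitability model.

#' Ground-truth suitability model
#'
#' Per-variable weights and per-category scores defining the "true"
#' preference surface the synthetic animals respond to. The surface is the
#' same weighted linear combination of categorized covariates the AHP engine
#' computes, so the generator and the expert-model path share one scoring
#' definition (see [ahp_suitability()]).
#'
#' Default weights make NDVI dominant in spring and distance-to-water
#' dominant in fall, echoing the seasonal contrast of the modelled system;
#' continuous variables are binned on edges scaled to the default 900 m
#' synthetic world.
#'
#' @param season `"spring"` or `"fall"`.
#' @param weights optional named 7-vector overriding the defaults
#'   (normalized to sum 1).
#' @return object of classes `truth_model` and `ahp_weights`.
#' @export
truth_model <- function(season = c("spring", "fall"), weights = NULL) {
  season <- match.arg(season)
  w <- if (season == "spring")
    c(dist_wells = 0.02, dist_water = 0.20, dist_roads = 0.11, ndvi = 0.40,
      fence = 0.02, landcover = 0.22, topo_position = 0.03)
  else
    c(dist_wells = 0.02, dist_water = 0.42, dist_roads = 0.06, ndvi = 0.23,
      fence = 0.03, landcover = 0.20, topo_position = 0.04)
  if (!is.null(weights)) {
    stopifnot(setequal(names(weights), COVARIATE_ROLES))
    w <- weights[names(w)] / sum(weights)
  }
  ndvi_scores <- if (season == "spring") c(`1` = 0.10, `2` = 0.40, `3` = 0.70, `4` = 1.00)
                 else                    c(`1` = 0.30, `2` = 1.00, `3` = 0.80, `4` = 0.40)
  structure(list(
    variable_weights = w / sum(w),
    category_scores = list(
      dist_wells = c(`1` = 0.20, `2` = 0.60, `3` = 1.00),   # near -> far
      dist_water = c(`1` = 1.00, `2` = 0.60, `3` = 0.20),   # near is best
      dist_roads = c(`1` = 0.20, `2` = 0.60, `3` = 1.00),
      ndvi = ndvi_scores,
      fence = c(`0` = 1.00, `1` = 0.30),                    # absent best
      landcover = c(`1` = 0.10, `2` = 0.05, `3` = 1.00, `4` = 0.60,
                    `5` = 0.40, `6` = 0.70),
      topo_position = c(`1` = 0.40, `2` = 1.00, `3` = 0.30, `4` = 0.50)),
    bin_edges = list(dist_wells = c(1500, 8000),
                     dist_water = c(1000, 10000),
                     dist_roads = c(1500, 5000),
                     ndvi = c(0.2, 0.3, 0.6)),
    season = season),
    class = c("truth_model", "ahp_weights"))
}

#' True suitability surface of a synthetic stack
#' @param stack a [covariate_stack()].
#' @param truth a [truth_model()].
#' @return continuous [raster_layer()] in `[0, 1]`.
#' @export
true_suitability <- function(stack, truth) ahp_suitability(stack, truth)

#' Generate the full synthetic landscape
#'
#' One call builds every shared structural element (terrain, land cover,
#' wells, water, roads, parcels, fences) plus the season-specific NDVI
#' layers, the two truth models and their suitability surfaces, and the
#' source/destination patch cell sets. Fully deterministic under
#' `params$seed`.
#'
#' @param params a [landscape_params()].
#' @return list with `stacks` (spring/fall [covariate_stack()]s), `truth`
#'   (spring/fall [truth_model()]s), `true_suit` (spring/fall layers),
#'   `parcels`, `roads`, `fences` (lines + raster), `patches` (list of cell
#'   index matrices: `source`, `dests`), `spec`.
#' @export
gen_landscape <- function(params) {
  sp <- grid_spec(params$nrows, params$ncols, params$cellsize)
  pr_out <- gen_parcels_and_roads(params)
  fences <- model_fences(pr_out$parcels, pr_out$roads, sp)

  base <- with_seed(params$seed + 202L, {
    elev <- smooth_field(params$nrows, params$ncols, params$corlen)
    lc_field <- smooth_field(params$nrows, params$ncols, params$corlen * 0.8)
    ndvi_base <- smooth_field(params$nrows, params$ncols, params$corlen * 0.6)
    wells_rc <- gen_well_cells(params)
    list(elev = elev, lc_field = lc_field, ndvi_base = ndvi_base,
         wells_rc = wells_rc)
  })

  # habitat patches as circular cell sets
  centers <- c(list(source = rel_to_cell(params, params$source_center)),
               stats::setNames(lapply(params$dest_centers, rel_to_cell,
                                      params = params),
                               paste0("dest", seq_along(params$dest_centers))))
  patch_cells <- lapply(centers, function(ctr)
    disk_cells(sp, ctr["row"], ctr["col"], params$patch_radius_cells))

  # land cover: quantile-threshold the smoothed field so target proportions
  # hold by construction, then force grassland on the habitat patches
  props <- params$landcover_props[c("water", "wetlands", "pasture",
                                    "agriculture", "development", "grassland")]
  qs <- cumsum(props)[-length(props)]
  edges <- stats::quantile(base$lc_field, qs, names = FALSE)
  codes_in_order <- LANDCOVER_CODES[c("water", "wetlands", "pasture",
                                      "agriculture", "development", "grassland")]
  lc <- matrix(codes_in_order[findInterval(base$lc_field, edges) + 1],
               params$nrows, params$ncols)
  for (pc in patch_cells) lc[pc] <- LANDCOVER_CODES[["grassland"]]
  landcover <- raster_layer(lc, sp, "categorical")

  # topographic position from the pseudo-elevation field
  tpi <- base$elev - smooth_wide(base$elev, params$corlen * 2)
  qt <- stats::quantile(tpi, c(0.10, 0.70, 0.85), names = FALSE)
  topo <- raster_layer(matrix(findInterval(tpi, qt) + 1, params$nrows,
                              params$ncols), sp, "categorical")

  # distance layers
  water_cells <- which(lc == LANDCOVER_CODES[["water"]], arr.ind = TRUE)
  extra_water <- with_seed(params$seed + 303L,
    cbind(sample(params$nrows, params$n_water_bodies, replace = TRUE),
          sample(params$ncols, params$n_water_bodies, replace = TRUE)))
  water_cells <- rbind(water_cells, extra_water)
  dist_water <- distance_to_features(sp, water_cells)
  if (nrow(base$wells_rc) == 0) stop("no wells requested: empty feature set")
  dist_wells <- distance_to_features(sp, base$wells_rc)
  road_cells <- which(rasterize_lines(sp, pr_out$roads)$values == 1,
                      arr.ind = TRUE)
  dist_roads <- distance_to_features(sp, road_cells)

  # seasonal NDVI: spring greens up near the northern destination patches;
  # fall greenness concentrates near water
  mk_ndvi <- function(season) {
    # spread greenness over the full [0, 1] range so all four NDVI
    # attribute bins are populated (the spring truth surface is
    # NDVI-dominated, so NDVI must carry real landscape variance)
    f <- 0.02 + 0.96 * base$ndvi_base
    if (season == "spring") {
      bump <- matrix(0, params$nrows, params$ncols)
      for (nm in names(patch_cells)[-1]) {
        ctr <- centers[[nm]]
        bump <- bump + gauss_bump(sp, ctr["row"], ctr["col"],
                                  4 * params$patch_radius_cells)
      }
      f <- f + 0.35 * pmin(bump, 1)
      f[patch_cells$source] <- pmax(f[patch_cells$source], 0.55)
    } else {
      f <- 0.7 * f + 0.3 * exp(-dist_water$values / 5000)
      for (nm in names(patch_cells)) f[patch_cells[[nm]]] <-
        pmax(f[patch_cells[[nm]]], 0.35)
    }
    raster_layer(pmin(pmax(f, 0), 1), sp, "continuous")
  }

  mk_stack <- function(season) covariate_stack(list(
    dist_wells = dist_wells, dist_water = dist_water, dist_roads = dist_roads,
    ndvi = mk_ndvi(season), fence = fences$raster, landcover = landcover,
    topo_position = topo), season)

  stacks <- list(spring = mk_stack("spring"), fall = mk_stack("fall"))
  truth <- list(spring = truth_model("spring"), fall = truth_model("fall"))
  true_suit <- list(spring = true_suitability(stacks$spring, truth$spring),
                    fall = true_suitability(stacks$fall, truth$fall))
  list(stacks = stacks, truth = truth, true_suit = true_suit,
       parcels = pr_out$parcels, roads = pr_out$roads, fences = fences,
       patches = list(source = patch_cells$source,
                      dests = patch_cells[-1]),
       centers = centers, spec = sp, params = params)
}

#' Generate a seasonal covariate stack
#'
#' Thin wrapper over [gen_landscape()] returning just the seven-layer stack
#' for one season.
#'
#' @param params a [landscape_params()].
#' @param season `"spring"` or `"fall"`.
#' @return a [covariate_stack()].
#' @export
gen_covariates <- function(params, season = c("spring", "fall")) {
  season <- match.arg(season)
  gen_landscape(params)$stacks[[season]]
}

#' Sample presence cells from a suitability surface
#'
#' Draws cells with probability proportional to `exp(effect * z)` where `z`
#' is the standardized suitability -- a Gibbs point process whose intensity
#' follows habitat quality. The default effect size of 1 puts a
#' presence-background AUC for a well-specified model near the high-0.6s /
#' low-0.7s, the regime reported for the modelled system.
#'
#' @param suitability continuous [raster_layer()].
#' @param n number of draws (duplicates removed, so the returned set can be
#'   smaller).
#' @param effect selection strength on standardized suitability.
#' @param seed integer seed.
#' @return vector of unique column-major linear cell indices.
#' @export
gen_presences <- function(suitability, n, effect = 1, seed = 1) {
  v <- valid_values(suitability)
  z <- (suitability$values - mean(v)) / stats::sd(v)
  cells <- which(!is.na(suitability$values))
  with_seed(seed,
    sort(unique(sample(cells, n, replace = TRUE,
                       prob = exp(effect * z[cells])))))
}

gen_well_cells <- function(params) {
  if (params$n_wells == 0) return(matrix(integer(0), ncol = 2))
  src <- rel_to_cell(params, params$source_center)
  r <- round(stats::rnorm(params$n_wells, src["row"], params$nrows * 0.08))
  c <- round(stats::rnorm(params$n_wells, src["col"], params$ncols * 0.12))
  cbind(pmin(pmax(r, 1), params$nrows), pmin(pmax(c, 1), params$ncols))
}

disk_cells <- function(spec, row, col, radius_cells) {
  rr <- max(1, floor(row - radius_cells)):min(spec$nrows, ceiling(row + radius_cells))
  cc <- max(1, floor(col - radius_cells)):min(spec$ncols, ceiling(col + radius_cells))
  g <- expand.grid(row = rr, col = cc)
  g <- g[(g$row - row)^2 + (g$col - col)^2 <= radius_cells^2, ]
  as.matrix(g)
}

gauss_bump <- function(spec, row, col, sd_cells) {
  r <- seq_len(spec$nrows); c <- seq_len(spec$ncols)
  outer(exp(-(r - row)^2 / (2 * sd_cells^2)),
        exp(-(c - col)^2 / (2 * sd_cells^2)))
}

smooth_wide <- function(m, corlen) {
  k <- function(n) {
    km <- stats::dnorm(outer(seq_len(n), seq_len(n), "-") / corlen)
    km / rowSums(km)
  }
  k(nrow(m)) %*% m %*% t(k(ncol(m)))
}
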