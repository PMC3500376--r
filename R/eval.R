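# Corridor evaluation: source/destination patch identification from a
# thresholded suitability surface, capture-rate statistics over the full
# season x HSM x connectivity x threshold factorial, per-individual
# containment, and the tiered priority-area overlay.

#' Equal-sensitivity/equal-specificity threshold
#'
#' Scans the sorted unique scores and returns the threshold minimizing
#' `|sensitivity - specificity|` where sensitivity = fraction of presence
#' scores >= t and specificity = fraction of background scores < t. Ties
#' resolve to the lowest threshold.
#'
#' @param presence_scores,background_scores numeric vectors.
#' @return threshold value.
#' @export
equal_sens_spec_threshold <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  cand <- sort(unique(c(presence_scores, background_scores)))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(background_scores < t), numeric(1))
  cand[which.min(abs(sens - spec))]   # which.min takes the lowest tie
}

#' Identify source and destination habitat patches
#'
#' Thresholds the suitability surface at the equal-sensitivity/specificity
#' point of presence vs background scores, labels 8-connected components of
#' the suitable mask, and assigns: source = component maximally overlapping
#' `source_hint` (the collaring area); destinations = components
#' overlapping each of `dest_hints` (e.g. high-density areas and a
#' protected-area polygon), ranked by within-component presence density.
#' If a destination hint lands in the same component as the source (one
#' connected blob of good habitat), the threshold is raised stepwise until
#' the components separate.
#'
#' @param suitability continuous [raster_layer()] in `[0, 1]`.
#' @param presence_cells linear cell indices of presences.
#' @param background_cells linear cell indices of the background sample.
#' @param source_hint cell set ((row, col) matrix or linear indices).
#' @param dest_hints list of cell sets.
#' @param min_cells minimum component size (cells), default 5.
#' @param max_steps threshold escalation steps (2.5% of the score range
#'   each), default 20.
#' @return object of class `patch_set`: list with `source` ((row, col)
#'   matrix), `dests` (list of matrices), `threshold`, `labels` (component
#'   raster).
#' @export
identify_patches <- function(suitability, presence_cells, background_cells,
                             source_hint, dest_hints, min_cells = 5,
                             max_steps = 20) {
  sp <- suitability$spec
  v <- suitability$values
  ps <- v[cells_to_linear(sp, presence_cells)]
  bs <- v[cells_to_linear(sp, background_cells)]
  t0 <- equal_sens_spec_threshold(ps[!is.na(ps)], bs[!is.na(bs)])
  rng <- range(valid_values(suitability))
  step <- 0.025 * diff(rng)
  src_lin <- cells_to_linear(sp, source_hint)
  dest_lin <- lapply(dest_hints, cells_to_linear, spec = sp)

  t <- t0
  source_comp <- NA_integer_
  dest_comps <- NA_integer_
  for (k in 0:max_steps) {
    mask <- !is.na(v) & v >= t
    if (!any(mask)) stop("no cell exceeds the suitability threshold")
    lab <- label_components(mask, 8L)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_cells)
    if (length(small)) lab[matrix(lab %in% small, nrow(lab))] <- 0L
    src_labs <- lab[src_lin]
    src_labs <- src_labs[src_labs > 0]
    if (length(src_labs) == 0) {
      if (k == 0) stop("source hint overlaps no suitable component")
      t <- t - step   # over-shot: previous threshold was the last workable
      next
    }
    source_comp <- as.integer(names(which.max(table(src_labs))))
    dest_comps <- vapply(dest_lin, function(dl) {
      dls <- lab[dl]; dls <- dls[dls > 0]
      if (length(dls) == 0) NA_integer_ else
        as.integer(names(which.max(table(dls))))
    }, integer(1))
    if (all(is.na(dest_comps)))
      stop("no destination hint overlaps a suitable component")
    # done when the source patch is distinct from every destination patch
    # and the destination hints resolve to distinct patches (the seasonal
    # design: one source, several separate destinations)
    dc <- stats::na.omit(dest_comps)
    separated <- !any(dc == source_comp) && !anyDuplicated(dc)
    if (separated || k == max_steps) break
    t <- t + step
  }
  if (any(stats::na.omit(dest_comps) == source_comp))
    stop("source and destination patches could not be separated")

  dest_comps_ok <- dest_comps[!is.na(dest_comps)]
  # rank destination components by presence density (presences per cell)
  pres_lab <- lab[cells_to_linear(sp, presence_cells)]
  dens <- vapply(unique(dest_comps_ok), function(cp)
    sum(pres_lab == cp, na.rm = TRUE) / sum(lab == cp), numeric(1))
  ord <- unique(dest_comps_ok)[order(dens, decreasing = TRUE)]
  structure(list(
    source = which(lab == source_comp, arr.ind = TRUE),
    dests = lapply(ord, function(cp) which(lab == cp, arr.ind = TRUE)),
    threshold = t, labels = lab),
    class = "patch_set")
}

#' @exportS3Method base::print
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set: source %d cells; %d destination patch(es) of %s cells; threshold %.4g>\n",
              nrow(x$source), length(x$dests),
              paste(vapply(x$dests, nrow, integer(1)), collapse = "/"),
              x$threshold))
}

#' Capture statistics of a corridor mask
#'
#' @param mask binary [raster_layer()].
#' @param points data.frame with `x`, `y` map coordinates.
#' @param valid_mask optional logical matrix defining the study-area
#'   denominator (defaults to the mask's valid cells).
#' @return named vector: `pct_points` (% of points whose cell is in the
#'   mask) and `pct_area` (% of valid cells in the mask).
#' @export
capture_stats <- function(mask, points, valid_mask = NULL) {
  if (nrow(points) == 0) stop("no points to evaluate")
  sp <- mask$spec
  if (is.null(valid_mask)) valid_mask <- !is.na(mask$values)
  rc <- coords_to_cell(sp, points$x, points$y)
  if (anyNA(rc)) stop("points outside the grid extent")
  inmask <- mask$values[cbind(rc[, 1], rc[, 2])] == 1
  inmask[is.na(inmask)] <- FALSE
  c(pct_points = 100 * mean(inmask),
    pct_area = 100 * sum(mask$values == 1, na.rm = TRUE) / sum(valid_mask))
}

#' Per-individual corridor containment
#'
#' @param mask binary [raster_layer()].
#' @param tracks named list of track data.frames.
#' @param windows named list of window detections (per individual).
#' @return data.frame: `id`, `n_fixes` (window fixes), `fraction` (inside
#'   mask), `fully_contained`.
#' @export
per_individual_capture <- function(mask, tracks, windows) {
  rows <- list()
  for (id in names(tracks)) {
    w <- windows[[id]]
    if (is.null(w) || !isTRUE(w$found)) next
    tr <- tracks[[id]]
    day <- as.Date(tr$t, tz = "UTC")
    sel <- day >= w$start & day <= w$end
    if (!any(sel)) next
    st <- capture_stats(mask, tr[sel, c("x", "y")])
    frac <- st[["pct_points"]] / 100
    rows[[id]] <- data.frame(id = id, n_fixes = sum(sel), fraction = frac,
                             fully_contained = frac == 1)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Full factorial corridor evaluation
#'
#' One record per season x HSM x connectivity method x threshold:
#' percentage of pooled migration fixes captured and percentage of study
#' area used, plus the count of fully contained individuals.
#'
#' @param corridors nested list `corridors[[season]][[hsm]][[method]]` of
#'   lists keyed by threshold (`"1"`, `"5"`, ...) of binary masks.
#' @param pools named list (season) of pooled presence data.frames.
#' @param tracks,windows as in [per_individual_capture()]; `windows` is a
#'   named list per season.
#' @return data.frame with 2 x 2 x 2 x (number of thresholds) rows.
#' @export
evaluation_matrix <- function(corridors, pools, tracks, windows) {
  rows <- list()
  for (season in names(corridors)) {
    for (hsm in names(corridors[[season]])) {
      for (method in names(corridors[[season]][[hsm]])) {
        masks <- corridors[[season]][[hsm]][[method]]
        for (thr in names(masks)) {
          mask <- masks[[thr]]
          st <- capture_stats(mask, pools[[season]])
          pic <- per_individual_capture(mask, tracks, windows[[season]])
          rows[[length(rows) + 1]] <- data.frame(
            season = season, hsm = hsm, method = method,
            threshold = as.numeric(thr),
            pct_points = st[["pct_points"]], pct_area = st[["pct_area"]],
            mean_individual_pct = 100 * mean(pic$fraction),
            n_fully_contained = sum(pic$fully_contained))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tiered priority-area overlay
#'
#' Tier 1 = union of the two seasonal 1% corridors; Tier 2 = intersection
#' of the seasonal 5% corridors; Tier 3 = intersection of the seasonal 10%
#' corridors. Each cell is coded by the best (lowest-numbered) tier it
#' attains; 0 = none. By per-season corridor nesting, Tier 2 is always a
#' subset of Tier 3.
#'
#' @param spring,fall named lists of binary masks keyed `"1"`, `"5"`,
#'   `"10"` (the seasonal best-model corridors).
#' @return categorical [raster_layer()] with codes 0-3.
#' @export
tier_map <- function(spring, fall) {
  need <- c("1", "5", "10")
  if (!all(need %in% names(spring)) || !all(need %in% names(fall)))
    stop("tier overlay needs the 1/5/10% corridors for both seasons")
  m <- function(x) ifelse(is.na(x$values), 0, x$values)
  tier1 <- pmin(m(spring[["1"]]) + m(fall[["1"]]), 1)
  tier2 <- m(spring[["5"]]) * m(fall[["5"]])
  tier3 <- m(spring[["10"]]) * m(fall[["10"]])
  code <- ifelse(tier1 == 1, 1, ifelse(tier2 == 1, 2, ifelse(tier3 == 1, 3, 0)))
  out <- raster_layer(code, spring[["1"]]$spec, "categorical")
  na <- is.na(spring[["1"]]$values)
  out$values[na] <- NA_real_
  out
}
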