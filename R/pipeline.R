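# End-to-end orchestration: simulate -> prep -> fit HSMs -> connect ->
# slice -> evaluate -> tiers, from one validated config, with per-stage
# logging and a content-hashed artifact manifest.

#' Default run configuration
#'
#' Nested list mirroring the pipeline stages. All randomness derives from
#' the single `seed`. Defaults encode the study design: 42 collared
#' individuals (17 spring / 18 fall migrants), 25% of presence points held
#' back for testing, corridor thresholds 1/5/10/15/20%, and a factor-3
#' grid aggregation for the circuit solves.
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    landscape = list(nrows = 120, ncols = 120, cellsize = 900),
    telemetry = list(n_individuals = 42, spring_migrants = 17,
                     fall_migrants = 18, fix_interval_h = 2),
    hsm = list(beta = 0.5, background_n = 10000, test_frac = 0.25,
               dedupe = TRUE, n_experts_spring = 11, n_experts_fall = 12,
               survey_noise_sd = 0.15),
    connectivity = list(neighbourhood = 8, circuit_aggregation = 3,
                        slicing_basis = "area_percentile"),
    thresholds = c(1, 5, 10, 15, 20),
    window = list(k = 1.25, floor_m = 5000)
  )
}

#' Validate a raw configuration
#'
#' Schema-checks a config list against [default_config()]: unknown keys are
#' rejected with their paths, missing keys filled with defaults, basic type
#' and range constraints enforced. A seed must be present.
#'
#' @param raw configuration list (e.g. parsed from JSON).
#' @return validated, fully populated config.
#' @export
validate_config <- function(raw) {
  if (is.null(raw$seed)) stop("config error at $seed: a seed is required")
  def <- default_config(raw$seed)
  check_keys <- function(r, d, path) {
    unknown <- setdiff(names(r), names(d))
    if (length(unknown))
      stop("config error: unknown key(s) ",
           paste0(path, "$", unknown, collapse = ", "))
    for (nm in names(r)) {
      if (is.list(d[[nm]]) && !is.null(names(d[[nm]])))
        check_keys(r[[nm]], d[[nm]], paste0(path, "$", nm))
    }
  }
  check_keys(raw, def, "")
  cfg <- utils::modifyList(def, raw)
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("config error at $seed: integer required")
  if (any(cfg$thresholds <= 0 | cfg$thresholds > 100))
    stop("config error at $thresholds: values must lie in (0, 100]")
  if (!cfg$connectivity$slicing_basis %in% c("area_percentile", "value_range"))
    stop("config error at $connectivity$slicing_basis")
  if (cfg$hsm$test_frac <= 0 || cfg$hsm$test_frac >= 1)
    stop("config error at $hsm$test_frac: must lie in (0, 1)")
  cfg
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

points_to_cells <- function(spec, points, dedupe = TRUE) {
  rc <- coords_to_cell(spec, points$x, points$y)
  lin <- rc[, 1] + (rc[, 2] - 1L) * spec$nrows
  lin <- lin[!is.na(lin)]
  if (dedupe) sort(unique(lin)) else lin
}

# Map fine-grid patch cells onto the aggregated grid.
aggregate_cells <- function(cells_rc, factor) {
  rc <- unique(cbind((cells_rc[, 1] - 1L) %/% factor + 1L,
                     (cells_rc[, 2] - 1L) %/% factor + 1L))
  rc
}

# Coarse cells shared between aggregated patches are kept by the first
# region that claims them (supernodes must be disjoint); regions emptied by
# the dedup are dropped.
disjoint_regions <- function(regions) {
  seen <- character(0)
  out <- list()
  for (r in regions) {
    key <- paste(r[, 1], r[, 2])
    r <- r[!key %in% seen, , drop = FALSE]
    seen <- c(seen, setdiff(key, seen))
    if (nrow(r) > 0) out[[length(out) + 1]] <- r
  }
  out
}

#' Run the full corridor pipeline
#'
#' @param config validated config from [validate_config()] /
#'   [default_config()].
#' @param out_dir output directory for artifacts (created if missing);
#'   `NULL` skips writing and returns results only.
#' @return list with `land`, `sim`, `prep` (windows, classifications,
#'   pools), `hsm` (per season: maxent fit/AUC/contributions/suitability/
#'   resistance and AHP weights/suitability/resistance), `patches`,
#'   `corridors`, `evaluation` (the 40-row table), `tiers`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  seed <- as.integer(config$seed)
  seasons <- c("spring", "fall")

  pipeline_log("simulate", "landscape %dx%d @ %gm, seed %d",
               config$landscape$nrows, config$landscape$ncols,
               config$landscape$cellsize, seed)
  lp <- do.call(landscape_params, c(config$landscape, list(seed = seed)))
  land <- gen_landscape(lp)
  tp <- do.call(telemetry_params, c(config$telemetry, list(seed = seed + 1L)))
  sim <- gen_tracks(land, tp)

  pipeline_log("prep", "windows + classification for %d individuals",
               length(sim$tracks))
  prep <- list()
  for (season in seasons) {
    windows <- lapply(sim$tracks, function(tr)
      tryCatch(detect_season_window(tr, season, k = config$window$k,
                                    floor_m = config$window$floor_m),
               error = function(e) list(found = FALSE)))
    cls <- vapply(names(sim$tracks), function(id)
      tryCatch(classify_long_distance(sim$tracks[[id]], season,
                                      window = windows[[id]]),
               error = function(e) NA_character_), character(1))
    migrants <- names(cls)[!is.na(cls) & cls == "migrant"]
    pool <- pool_migration_points(sim$tracks[migrants], season,
                                  windows[migrants])
    prep[[season]] <- list(windows = windows, classification = cls,
                           migrants = migrants, pool = pool)
    pipeline_log("prep", "%s: %d migrants, %d pooled fixes", season,
                 length(migrants), nrow(pool))
  }

  hsm <- list()
  for (season in seasons) {
    stack <- land$stacks[[season]]
    features <- build_features(stack, exclude = "dist_wells")
    pres <- points_to_cells(stack$spec, prep[[season]]$pool,
                            dedupe = config$hsm$dedupe)
    split <- split_points(pres, config$hsm$test_frac, seed = seed + 3L)
    bg <- sample_background(features, config$hsm$background_n,
                            seed = seed + 2L)
    fit <- fit_maxent(features, split$train, bg, beta = config$hsm$beta)
    suit <- predict(fit, features, mode = "logistic")
    raw <- predict(fit, features, mode = "raw")
    test_scores <- suit$values[split$test]
    bg_scores <- suit$values[bg]
    auc <- auc_presence_background(test_scores, bg_scores)
    contrib <- variable_contributions(fit)
    mx_res <- suitability_to_resistance(raw, mode = "maxent")
    pipeline_log("hsm", "%s maxent: %d train / %d test cells, AUC %.3f",
                 season, length(split$train), length(split$test), auc)

    n_exp <- if (season == "spring") config$hsm$n_experts_spring else
      config$hsm$n_experts_fall
    surveys <- gen_expert_surveys(land$truth[[season]], n_experts = n_exp,
                                  noise_sd = config$hsm$survey_noise_sd,
                                  seed = seed + 4L + match(season, seasons))
    weights <- surveys_to_weights(surveys, land$truth[[season]]$bin_edges)
    ahp_suit <- ahp_suitability(stack, weights)
    ahp_res <- invert_rescale(ahp_suit)
    hsm[[season]] <- list(
      features = features, presence = pres, split = split, background = bg,
      maxent = list(fit = fit, suitability = suit, raw = raw, auc = auc,
                    contributions = contrib, resistance = mx_res),
      ahp = list(surveys = surveys, weights = weights,
                 suitability = ahp_suit, resistance = ahp_res))
  }

  pipeline_log("patches", "identifying habitat patches on spring maxent HSM")
  patches <- identify_patches(
    hsm$spring$maxent$suitability,
    presence_cells = hsm$spring$presence,
    background_cells = hsm$spring$background,
    source_hint = land$patches$source,
    dest_hints = land$patches$dests)

  src_cells <- patches$source
  dest_cells_list <- patches$dests
  dest_union <- do.call(rbind, dest_cells_list)
  thr <- config$thresholds
  fac <- config$connectivity$circuit_aggregation
  basis <- config$connectivity$slicing_basis

  corridors <- list()
  circuit_info <- list()
  for (season in seasons) {
    corridors[[season]] <- list()
    for (h in c("maxent", "ahp")) {
      resist <- hsm[[season]][[h]]$resistance
      cs <- lcm_corridor_surface(resist, src_cells, dest_union)
      lcm_masks <- stats::setNames(lapply(thr, function(p)
        slice_corridor(cs, p, basis,
                       provenance = list(season = season, hsm = h,
                                         method = "lcm"))),
        as.character(thr))

      r_coarse <- if (fac > 1) resample(resist, fac, "mean") else resist
      focal <- disjoint_regions(
        c(list(aggregate_cells(src_cells, fac)),
          lapply(dest_cells_list, aggregate_cells, factor = fac)))
      cur <- cumulative_current(r_coarse, focal,
                                neighbourhood = config$connectivity$neighbourhood)
      cir_masks <- stats::setNames(lapply(thr, function(p)
        slice_current(cur$current, p, focal_regions = focal[1:2],
                      provenance = list(season = season, hsm = h,
                                        method = "circuit"))),
        as.character(thr))
      corridors[[season]][[h]] <- list(lcm = lcm_masks, circuit = cir_masks)
      circuit_info[[paste(season, h)]] <- cur$R_eff
      pipeline_log("connect", "%s/%s: LCM + circuit corridors at %s%%",
                   season, h, paste(thr, collapse = "/"))
    }
  }

  pools <- lapply(prep, `[[`, "pool")
  windows_by_season <- lapply(prep, `[[`, "windows")
  evaluation <- evaluation_matrix(corridors, pools,
                                  tracks = sim$tracks,
                                  windows = windows_by_season)
  pipeline_log("evaluate", "%d evaluation records", nrow(evaluation))

  tiers <- NULL
  if (all(c("1", "5", "10") %in% as.character(thr))) {
    tiers <- tier_map(corridors$spring$maxent$lcm,
                      corridors$fall$maxent$lcm)
  }

  result <- list(config = config, land = land, sim = sim, prep = prep,
                 hsm = hsm, patches = patches, corridors = corridors,
                 circuit_R_eff = circuit_info, evaluation = evaluation,
                 tiers = tiers)
  if (!is.null(out_dir)) result$manifest <- write_artifacts(result, out_dir)
  result
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(rel) { p <- file.path(out_dir, rel); paths <<- c(paths, p); p }

  for (season in names(result$hsm)) {
    write_raster(result$hsm[[season]]$maxent$suitability,
                 put(sprintf("suitability_maxent_%s.asc", season)))
    write_raster(result$hsm[[season]]$ahp$suitability,
                 put(sprintf("suitability_ahp_%s.asc", season)))
    write_raster(result$hsm[[season]]$maxent$resistance,
                 put(sprintf("resistance_maxent_%s.asc", season)))
    write_raster(result$hsm[[season]]$ahp$resistance,
                 put(sprintf("resistance_ahp_%s.asc", season)))
    utils::write.csv(
      data.frame(variable = names(result$hsm[[season]]$maxent$contributions),
                 pct_contribution = as.numeric(result$hsm[[season]]$maxent$contributions)),
      put(sprintf("contributions_maxent_%s.csv", season)), row.names = FALSE)
  }
  utils::write.csv(result$evaluation, put("evaluation.csv"), row.names = FALSE)
  if (!is.null(result$tiers))
    write_raster(result$tiers, put("tier_map.asc"))
  write_tracks_csv(result$sim$tracks, put("tracks.csv"))
  cfg_path <- put("config.json")
  jsonlite::write_json(result$config, cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- data.frame(path = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  manifest
}

#' Command-line entry point
#'
#' `corridorscope run --config FILE --out DIR [--seed N]` runs the full
#' pipeline; `corridorscope default-config` prints the default
#' configuration as JSON. Exit codes: 0 ok, 1 user error, 2 internal
#' error.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit code, invisibly.
#' @export
corridorscope_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: corridorscope <run|default-config> [--config FILE] [--out DIR] [--seed N]\n")
  }
  getopt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  if (length(args) == 0) { usage(); return(invisible(1L)) }
  cmd <- args[1]
  out <- tryCatch({
    if (cmd == "default-config") {
      cat(jsonlite::toJSON(default_config(), auto_unbox = TRUE, pretty = TRUE,
                           digits = NA), "\n")
      0L
    } else if (cmd == "run") {
      cfg_file <- getopt("--config")
      raw <- if (is.null(cfg_file)) list(seed = 1) else
        jsonlite::read_json(cfg_file, simplifyVector = TRUE)
      seed_opt <- getopt("--seed")
      if (!is.null(seed_opt)) raw$seed <- as.integer(seed_opt)
      out_dir <- getopt("--out")
      if (is.null(out_dir)) { usage(); return(invisible(1L)) }
      cfg <- validate_config(raw)
      run_pipeline(cfg, out_dir)
      0L
    } else { usage(); 1L }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("^config error", conditionMessage(e))) 1L else 2L
  })
  invisible(out)
}
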