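# Synthetic migratory telemetry. The stated world: 42 collared individuals,
# 17 spring migrants and 18 fall migrants moving >50 km between a southern
# source patch and northern destination patches; daily movement averages
# 6,973 m during migration vs 4,827 m otherwise; ~300 fixes per migrant per
# migration window so the pooled spring presence set lands near 5,100
# points. Movement is a step-length/turning-angle walk: step lengths are
# tight around the daily budget, migration headings aim at the destination
# with adaptive directional noise (tortuosity) so each animal arrives as its
# window closes, and candidate headings are biased toward higher true
# suitability so corridors align with the truth surface.

#' Telemetry simulation parameters
#'
#' @param n_individuals collared population size.
#' @param spring_migrants,fall_migrants numbers of long-distance migrants by
#'   season; spring migrants are a subset of fall migrants' ids.
#' @param fix_interval_h hours between GPS fixes.
#' @param start_date,end_date tracking period (dates, same calendar year).
#' @param resident_daily_m,migration_daily_m mean daily movement (m) outside
#'   and during migration.
#' @param window_days migration window length in days.
#' @param spring_start_range,fall_start_range day-of-year windows from which
#'   each individual's migration start date is drawn.
#' @param noise overall stochasticity multiplier; 0 gives fully
#'   deterministic straight-line migrations and stationary residents.
#' @param suit_bias number of candidate headings scored against the true
#'   suitability surface per migration step (1 = no habitat bias).
#' @param seed integer seed.
#' @return object of class `telemetry_params`.
#' @export
telemetry_params <- function(n_individuals = 42, spring_migrants = 17,
                             fall_migrants = 18, fix_interval_h = 2,
                             start_date = "2008-02-01", end_date = "2008-12-31",
                             resident_daily_m = 4827, migration_daily_m = 6973,
                             window_days = 25,
                             spring_start_range = c("2008-03-20", "2008-04-10"),
                             fall_start_range = c("2008-10-05", "2008-10-25"),
                             noise = 1, suit_bias = 3, seed = 1) {
  stopifnot(spring_migrants <= fall_migrants,
            fall_migrants <= n_individuals, fix_interval_h > 0)
  structure(as.list(environment()), class = "telemetry_params")
}

#' Simulate the collared population
#'
#' @param land output of [gen_landscape()].
#' @param tp a [telemetry_params()].
#' @return list with `tracks` (named list of per-individual data.frames with
#'   `x`, `y`, `t`), `truth_windows` (data.frame: id, season, start, end as
#'   dates), `assignments` (data.frame: id, spring_migrant, fall_migrant,
#'   dest).
#' @export
gen_tracks <- function(land, tp = telemetry_params()) {
  sp <- land$spec
  fpd <- as.integer(round(24 / tp$fix_interval_h))
  t0 <- as.POSIXct(paste(tp$start_date, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(tp$end_date, "23:59:59"), tz = "UTC")
  times <- seq(t0, t1, by = tp$fix_interval_h * 3600)
  days <- as.Date(times, tz = "UTC")

  centers_xy <- lapply(land$centers, function(rc)
    cell_centers(sp, rc["row"], rc["col"])[1, ])
  dest_names <- setdiff(names(centers_xy), "source")

  suit <- list(spring = land$true_suit$spring$values,
               fall = land$true_suit$fall$values)
  xmin <- sp$origin_x + sp$cellsize; xmax <- sp$origin_x + (sp$ncols - 1) * sp$cellsize
  ymin <- sp$origin_y - (sp$nrows - 1) * sp$cellsize; ymax <- sp$origin_y - sp$cellsize

  suit_at <- function(season, x, y) {
    rc <- coords_to_cell(sp, x, y)
    s <- suit[[season]][cbind(rc[, 1], rc[, 2])]
    s[is.na(s)] <- 0
    s
  }

  with_seed(tp$seed + 404L, {
    ids <- sprintf("ind%02d", seq_len(tp$n_individuals))
    spring_ids <- ids[seq_len(tp$spring_migrants)]
    fall_ids <- ids[seq_len(tp$fall_migrants)]
    dest_assign <- stats::setNames(
      dest_names[(seq_len(tp$n_individuals) - 1) %% length(dest_names) + 1], ids)

    day_seq <- function(rng) {
      d0 <- as.Date(rng[1]); d1 <- as.Date(rng[2])
      d0 + sample.int(as.integer(d1 - d0) + 1L, 1L) - 1L
    }

    tracks <- list(); wins <- list(); assign_rows <- list()
    for (id in ids) {
      is_spring <- id %in% spring_ids
      is_fall <- id %in% fall_ids
      dest_xy <- centers_xy[[dest_assign[[id]]]]
      src_xy <- centers_xy$source
      # residents get a home near the source patch; a fall-only migrant
      # summers on its destination patch from the start
      home0 <- if (!is_spring && is_fall) dest_xy else
        src_xy + tp$noise * stats::rnorm(2, 0, 3 * sp$cellsize)

      w_spring <- if (is_spring) {
        s <- day_seq(tp$spring_start_range); c(s, s + tp$window_days - 1)
      } else NULL
      w_fall <- if (is_fall) {
        s <- day_seq(tp$fall_start_range); c(s, s + tp$window_days - 1)
      } else NULL

      xy <- simulate_path(times, days, fpd, home0, src_xy, dest_xy,
                          w_spring, w_fall, is_spring, is_fall, tp, sp,
                          suit_at, c(xmin, xmax, ymin, ymax))
      tracks[[id]] <- data.frame(x = xy[, 1], y = xy[, 2], t = times)
      if (is_spring) wins[[paste0(id, "_sp")]] <-
        data.frame(id = id, season = "spring", start = w_spring[1], end = w_spring[2])
      if (is_fall) wins[[paste0(id, "_fa")]] <-
        data.frame(id = id, season = "fall", start = w_fall[1], end = w_fall[2])
      assign_rows[[id]] <- data.frame(id = id, spring_migrant = is_spring,
                                      fall_migrant = is_fall,
                                      dest = dest_assign[[id]])
    }
    list(tracks = tracks,
         truth_windows = do.call(rbind, unname(wins)),
         assignments = do.call(rbind, unname(assign_rows)))
  })
}

# One individual's full-year path.
simulate_path <- function(times, days, fpd, home0, src_xy, dest_xy,
                          w_spring, w_fall, is_spring, is_fall, tp, sp,
                          suit_at, bbox) {
  n <- length(times)
  L_res <- tp$resident_daily_m / fpd
  L_mig <- tp$migration_daily_m / fpd
  xy <- matrix(0, n, 2)
  pos <- home0
  home <- home0
  season_of <- function(day) {
    if (!is.null(w_spring) && day >= w_spring[1] && day <= w_spring[2]) "spring_mig"
    else if (!is.null(w_fall) && day >= w_fall[1] && day <= w_fall[2]) "fall_mig"
    else "resident"
  }
  # per-fix phase, and fixes remaining in the current contiguous phase run
  phase <- vapply(days, season_of, character(1))
  runs <- rle(phase)
  rem <- unlist(lapply(runs$lengths, function(l) rev(seq_len(l))),
                use.names = FALSE)
  for (i in seq_len(n)) {
    ph <- phase[i]
    if (ph == "resident") {
      if (i > 1 && phase[i - 1] == "spring_mig") home <- dest_xy
      if (i > 1 && phase[i - 1] == "fall_mig") home <- src_xy
      if (tp$noise == 0) {
        pos <- home
      } else {
        ang <- stats::runif(1, 0, 2 * pi)
        pull <- 0.10 * (home - pos)
        step <- L_res * exp(tp$noise * stats::rnorm(1, 0, 0.08) - 0.0032)
        pos <- pos + pull + step * c(cos(ang), sin(ang))
      }
    } else {
      tgt <- if (ph == "spring_mig") dest_xy else src_xy
      rem_steps <- rem[i]
      to_tgt <- tgt - pos
      dist <- sqrt(sum(to_tgt^2))
      need <- dist / max(rem_steps, 1)
      if (tp$noise == 0) {
        # deterministic: straight path, uniform pace, exact arrival
        pos <- if (dist <= need || rem_steps <= 1) tgt else
          pos + to_tgt / dist * need
      } else {
        # steady travel budget: small length noise keeps daily displacement
        # several sigma above the window-detection threshold
        L <- L_mig * exp(tp$noise * stats::rnorm(1, 0, 0.05) - 0.00125)
        ecos <- min(max(need / L, 0.05), 0.98)
        s <- sqrt(-2 * log(ecos))           # wrapped-normal heading sd
        base_ang <- atan2(to_tgt[2], to_tgt[1])
        k <- max(1L, as.integer(tp$suit_bias))
        cand_ang <- base_ang + stats::rnorm(k, 0, s)
        cx <- pos[1] + L * cos(cand_ang); cy <- pos[2] + L * sin(cand_ang)
        sv <- suit_at(if (ph == "spring_mig") "spring" else "fall", cx, cy)
        j <- which.max(sv + stats::runif(k, 0, 1e-9))
        pos <- c(cx[j], cy[j])
        if (sqrt(sum((tgt - pos)^2)) < 0.75 * sp$cellsize) pos <- tgt
      }
    }
    pos[1] <- min(max(pos[1], bbox[1]), bbox[2])
    pos[2] <- min(max(pos[2], bbox[3]), bbox[4])
    xy[i, ] <- pos
  }
  xy
}
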