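test_that("equal sensitivity/specificity threshold by enumeration", {
  # separated scores: lowest workable threshold returned
  t1 <- equal_sens_spec_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(t1, 0.8)
  # identical distributions: sens ~ spec ~ 0.5 near the median
  set.seed(5)
  x <- runif(400)
  tm <- equal_sens_spec_threshold(x, x)
  expect_lt(abs(mean(x >= tm) - 0.5), 0.06)

  pres <- c(0.9, 0.8, 0.3); bg <- c(0.7, 0.2, 0.1)
  t3 <- equal_sens_spec_threshold(pres, bg)
  cand <- sort(unique(c(pres, bg)))
  gaps <- sapply(cand, function(t) abs(mean(pres >= t) - mean(bg < t)))
  expect_equal(t3, cand[which.min(gaps)])
})

test_that("capture statistics are exact on constructed fixtures", {
  sp <- grid_spec(10, 10, 100)
  mask <- matrix(0, 10, 10); mask[1:5, 1:5] <- 1   # 25 of 100 cells
  ml <- raster_layer(mask, sp, "binary")
  # 7 of 10 points inside the mask
  inside <- cell_centers(sp, c(1, 2, 3, 4, 5, 1, 2), c(1, 1, 2, 3, 4, 5, 5))
  outside <- cell_centers(sp, c(8, 9, 10), c(8, 9, 10))
  pts <- as.data.frame(rbind(inside, outside))
  st <- capture_stats(ml, pts)
  expect_equal(unname(st["pct_points"]), 70)
  expect_equal(unname(st["pct_area"]), 25)

  all_mask <- raster_layer(matrix(1, 10, 10), sp, "binary")
  expect_equal(unname(capture_stats(all_mask, pts)), c(100, 100))
  none <- raster_layer(matrix(0, 10, 10), sp, "binary")
  expect_equal(unname(capture_stats(none, pts)), c(0, 0))
  expect_error(capture_stats(ml, pts[0, ]), "no points")
  far <- data.frame(x = 1e9, y = 1e9)
  expect_error(capture_stats(ml, far), "outside")
})

test_that("per-individual capture equals brute-force point-in-mask counts", {
  sp <- grid_spec(10, 10, 100)
  mask <- matrix(0, 10, 10); mask[, 1:5] <- 1
  ml <- raster_layer(mask, sp, "binary")
  t0 <- as.POSIXct("2008-04-01", tz = "UTC")
  mk <- function(cols) {
    ctr <- cell_centers(sp, seq_along(cols), cols)
    data.frame(x = ctr[, 1], y = ctr[, 2], t = t0 + seq_along(cols) * 3600)
  }
  tracks <- list(in_all = mk(c(1, 2, 3)), out_all = mk(c(6, 7, 8)),
                 half = mk(c(1, 2, 6, 7)))
  wins <- lapply(tracks, function(.)
    list(found = TRUE, start = as.Date("2008-04-01"),
         end = as.Date("2008-04-02")))
  tab <- per_individual_capture(ml, tracks, wins)
  expect_equal(tab$fraction[tab$id == "in_all"], 1)
  expect_true(tab$fully_contained[tab$id == "in_all"])
  expect_equal(tab$fraction[tab$id == "out_all"], 0)
  expect_equal(tab$fraction[tab$id == "half"], 0.5)
})

test_that("tier overlay set algebra", {
  sp <- grid_spec(8, 8, 100)
  mk <- function(rows, cols) {
    m <- matrix(0, 8, 8); m[rows, cols] <- 1
    raster_layer(m, sp, "binary")
  }
  # nested seasonal corridors sharing a core
  spring <- list(`1` = mk(4, 4:5), `5` = mk(3:5, 3:6), `10` = mk(2:6, 2:7))
  fall <- list(`1` = mk(5, 4:5), `5` = mk(4:6, 3:6), `10` = mk(3:7, 2:7))
  tm <- tier_map(spring, fall)
  # tier 1 = union of the 1% corridors
  expect_equal(sum(tm$values == 1), 4)
  t2cells <- which(tm$values == 2)
  t3cells <- which(tm$values == 3)
  # tier 2 region (5% intersection) always nests inside tier 3 (10% inter.)
  t2region <- spring[["5"]]$values * fall[["5"]]$values
  t3region <- spring[["10"]]$values * fall[["10"]]$values
  expect_true(all(t3region[t2region == 1] == 1))

  # disjoint seasonal 5% corridors -> empty tier 2
  fall_dis <- list(`1` = mk(8, 8), `5` = mk(7:8, 7:8), `10` = mk(6:8, 6:8))
  tm2 <- tier_map(spring, fall_dis)
  expect_equal(sum(tm2$values == 2), 0)
  expect_error(tier_map(spring[c("1", "5")], fall), "1/5/10")

  # random masks: tier2 subset tier3 whenever per-season nesting holds
  set.seed(40)
  for (k in 1:5) {
    base_s <- matrix(runif(64), 8, 8); base_f <- matrix(runif(64), 8, 8)
    sl <- function(b, q) raster_layer((b <= quantile(b, q)) * 1, sp, "binary")
    sp_masks <- list(`1` = sl(base_s, 0.01), `5` = sl(base_s, 0.05),
                     `10` = sl(base_s, 0.10))
    fa_masks <- list(`1` = sl(base_f, 0.01), `5` = sl(base_f, 0.05),
                     `10` = sl(base_f, 0.10))
    tmk <- tier_map(sp_masks, fa_masks)
    t2 <- sp_masks[["5"]]$values * fa_masks[["5"]]$values
    t3 <- sp_masks[["10"]]$values * fa_masks[["10"]]$values
    expect_true(all(t3[t2 == 1] == 1))
  }
})

test_that("patch identification on a constructed two-blob landscape", {
  sp <- grid_spec(30, 30, 100)
  s <- matrix(0.2, 30, 30)
  s[3:8, 3:8] <- 0.9        # destination blob (north-west rows are top)
  s[22:27, 22:27] <- 0.85   # source blob
  suit <- raster_layer(s, sp)
  pres <- which(s >= 0.8)   # presences on both blobs
  bg <- seq(1, 900, by = 3)
  ps <- identify_patches(suit, pres, bg,
                         source_hint = cbind(24, 24),
                         dest_hints = list(cbind(5, 5)))
  expect_s3_class(ps, "patch_set")
  expect_equal(length(ps$dests), 1)
  # source component covers the source blob
  expect_true(all(ps$source[, 1] %in% 22:27))
  expect_true(all(ps$dests[[1]][, 1] %in% 3:8))
  expect_error(identify_patches(suit, pres, bg,
                                source_hint = cbind(15, 15),
                                dest_hints = list(cbind(5, 5))),
               "source hint")
})
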