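# A tiny hand-built feature universe: n cells with explicit features.
manual_features <- function(X, cellsize = 30) {
  n <- nrow(X)
  structure(list(X = X,
                 feature_names = colnames(X),
                 variable = if (is.null(attr(X, "variable")))
                   colnames(X) else attr(X, "variable"),
                 cells = seq_len(n), spec = grid_spec(1, n, cellsize)),
            class = "feature_matrix")
}

test_that("feature construction counts, exclusion and degenerate inputs", {
  land <- default_land()
  f <- build_features(land$stacks$spring, exclude = "dist_wells")
  expect_false(any(grepl("wells", f$feature_names)))
  # 3 continuous x 2 + fence 2 + landcover 6 + topo 4 = 18
  expect_equal(ncol(f$X), 18)
  conts <- grep(":lin$|:quad$", f$feature_names)
  expect_equal(unname(colMeans(f$X[, conts])), rep(0, length(conts)),
               tolerance = 1e-9)
  expect_equal(unname(apply(f$X[, conts], 2, sd)), rep(1, length(conts)),
               tolerance = 1e-9)

  # constant covariate errors
  land2 <- land$stacks$spring
  land2$layers$ndvi$values[] <- 0.5
  expect_error(build_features(land2), "zero variance")
})

test_that("beta = 0 maxent matches the empirical distribution on a toy", {
  X <- diag(5); colnames(X) <- paste0("c", 1:5)
  f <- manual_features(X)
  pres <- rep(1:5, times = c(6, 2, 4, 3, 5))
  fit <- fit_maxent(f, pres, 1:5, beta = 0)
  q <- predict(fit, f, "raw")
  expect_equal(as.numeric(q$values), as.numeric(table(pres) / length(pres)),
               tolerance = 1e-5)
  expect_equal(sum(q$values), 1, tolerance = 1e-9)
  # objective gains all positive, trace present
  expect_true(all(fit$gain_trace$gain > 0))
})

test_that("null data keeps coefficients near zero; signal sets the sign", {
  set.seed(8)
  z <- rnorm(4000)
  X <- cbind(f1 = (z - mean(z)) / sd(z))
  f <- manual_features(X)
  pres_null <- sample(4000, 2000, replace = TRUE)     # uniform presences
  fit0 <- fit_maxent(f, pres_null, 1:4000, beta = 0.1)
  expect_lt(max(abs(fit0$lambda)), 0.05)

  pres_hi <- order(z, decreasing = TRUE)[1:500]       # concentrated high-f1
  fit1 <- fit_maxent(f, pres_hi, 1:4000, beta = 0.5)
  expect_gt(fit1$lambda[["f1"]], 0)
})

test_that("constraint satisfaction holds on a converged landscape fit", {
  land <- default_land()
  f <- build_features(land$stacks$spring)
  bg <- sample_background(f, 4000, seed = 2)
  pres <- gen_presences(land$true_suit$spring, 1200, seed = 3)
  fit <- fit_maxent(f, pres, bg)
  Xb <- f$X[match(bg, f$cells), ]
  Xp <- f$X[match(pres, f$cells), ]
  eta <- as.numeric(Xb %*% fit$lambda)
  w <- exp(eta - max(eta)); w <- w / sum(w)
  gap <- abs(colSums(w * Xb) - colMeans(Xp))
  expect_true(all(gap <= fit$beta + 1e-6))
  # raw normalization over the background
  raw <- predict(fit, f, "raw")
  expect_equal(sum(raw$values[bg]), 1, tolerance = 1e-9)
  # log mode is rank-identical to raw
  lg <- predict(fit, f, "log")
  expect_equal(rank(raw$values[f$cells]), rank(lg$values[f$cells]))
})

test_that("uniform model predicts logistic 0.5 everywhere", {
  X <- cbind(f1 = rep(c(-1, 1), 10))
  f <- manual_features(X)
  fit <- fit_maxent(f, rep(1:20, 2), 1:20, beta = 50)  # heavy shrinkage
  expect_equal(max(abs(fit$lambda)), 0)
  p <- predict(fit, f, "logistic")
  expect_equal(as.numeric(p$values), rep(0.5, 20))
})

test_that("split_points is seeded, disjoint, exhaustive, with 75/25 sizes", {
  s <- split_points(1:100, 0.25, seed = 9)
  expect_equal(length(s$test), 25)
  expect_equal(length(s$train), 75)
  expect_setequal(c(s$train, s$test), 1:100)
  s2 <- split_points(1:100, 0.25, seed = 9)
  expect_identical(s, s2)
  s3 <- split_points(seq_len(5364), 0.25, seed = 1)
  expect_equal(length(s3$train), 4023)
  expect_equal(length(s3$test), 1341)
  expect_error(split_points(1:5), "at least 8")
})

test_that("AUC follows the Mann-Whitney definition", {
  expect_equal(auc_presence_background(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc_presence_background(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc_presence_background(c(0.5, 0.7), c(0.5, 0.7)), 0.5)
  set.seed(3)   # identical distributions -> 0.5 in expectation
  a <- replicate(200, auc_presence_background(runif(20), runif(20)))
  expect_lt(abs(mean(a) - 0.5), 0.03)
})

test_that("contributions: single variable gets 100%, sums normalize", {
  X <- cbind(f1 = rep(c(-1, 1), 20)); attr(X, "variable") <- "only_var"
  f <- manual_features(X)
  fit <- fit_maxent(f, rep(which(X[, 1] > 0), 2), 1:40, beta = 0.01)
  vc <- variable_contributions(fit)
  expect_equal(unname(vc["only_var"]), 100)

  land <- default_land()
  fl <- build_features(land$stacks$spring)
  bg <- sample_background(fl, 4000, seed = 2)
  pres <- gen_presences(land$true_suit$spring, 800, seed = 5)
  vc2 <- variable_contributions(fit_maxent(fl, pres, bg))
  expect_equal(sum(vc2), 100, tolerance = 0.1)
})

test_that("jackknife: noise variables gain ~0, duplicates are redundant", {
  set.seed(12)
  n <- 2000
  sig <- rnorm(n); noise <- rnorm(n)
  X <- cbind(sig = scale(sig)[, 1], dup = scale(sig)[, 1],
             noise = scale(noise)[, 1])
  attr(X, "variable") <- c("sig", "dup", "noise")
  f <- manual_features(X)
  pres <- sample(n, 600, replace = TRUE, prob = exp(1.2 * X[, 1]))
  fit_one <- function(keep) {
    X1 <- X[, keep, drop = FALSE]; attr(X1, "variable") <- keep
    fit_maxent(manual_features(X1), pres, 1:n, beta = 0.5)$objective
  }
  g_noise_only <- fit_one("noise")
  g_full <- fit_one(c("sig", "dup", "noise"))
  g_wo_dup <- fit_one(c("sig", "noise"))
  expect_lt(g_noise_only, 0.02)            # pure noise explains ~nothing
  expect_lt(abs(g_full - g_wo_dup), 0.02)  # withholding a duplicate costs ~0
  expect_gte(g_full, 0)                    # gains non-negative vs the null
})

test_that("suitability-to-resistance inverts rank order onto [r_min, 1]", {
  set.seed(4)
  sp <- grid_spec(6, 6, 30)
  raw <- raster_layer(matrix(exp(rnorm(36, -8)), 6, 6), sp)
  r <- suitability_to_resistance(raw, "maxent")
  v <- valid_values(r)
  expect_equal(min(v), 0.01)
  expect_equal(max(v), 1)
  expect_equal(rank(-valid_values(raw)), rank(valid_values(r)))
  expect_error(suitability_to_resistance(
    raster_layer(matrix(0.3, 6, 6), sp), "maxent"), "degenerate")
})
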