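test_that("principal weights: uniform, consistent and random-matrix oracle", {
  pw <- principal_weights(pairwise_matrix(matrix(1, 3, 3)))
  expect_equal(unname(pw$weights), rep(1 / 3, 3))
  expect_equal(pw$lambda_max, 3, tolerance = 1e-9)

  w <- c(0.5, 0.3, 0.2)
  pw2 <- principal_weights(pairwise_matrix(outer(w, w, "/")))
  expect_equal(unname(pw2$weights), w, tolerance = 1e-9)
  expect_equal(pw2$lambda_max, 3, tolerance = 1e-9)

  # random reciprocal matrices vs dense eigen-decomposition, n = 4..7
  set.seed(21)
  for (n in 4:7) {
    m <- diag(n) * 0 + 1
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- exp(runif(1, -1.5, 1.5))
      m[i, j] <- min(max(r, 1 / 9), 9); m[j, i] <- 1 / m[i, j]
    }
    diag(m) <- 1
    pm <- pairwise_matrix(m)
    got <- principal_weights(pm)
    ev <- eigen(m)
    k <- which.max(Re(ev$values))
    vec <- Re(ev$vectors[, k]); vec <- vec / sum(vec)
    expect_equal(unname(got$weights), vec, tolerance = 1e-8)
    expect_equal(got$lambda_max, Re(ev$values[k]), tolerance = 1e-8)
  }

  bad <- matrix(c(1, 2, 3, 1), 2, 2)
  expect_error(pairwise_matrix(bad), "reciprocal")
})

test_that("consistency ratio: zero for consistent, flags intransitivity", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  cr <- consistency_ratio(pairwise_matrix(outer(w, w, "/")))
  expect_equal(cr$CR, 0, tolerance = 1e-9)
  expect_false(cr$flagged)

  w7 <- rep(1 / 7, 7)
  expect_equal(consistency_ratio(pairwise_matrix(outer(w7, w7, "/")))$CI, 0,
               tolerance = 1e-12)

  bad <- matrix(c(1, 9, 1 / 9,   1 / 9, 1, 9,   9, 1 / 9, 1), 3, 3,
                byrow = TRUE)
  expect_warning(cr3 <- consistency_ratio(pairwise_matrix(bad)), "0.1")
  expect_gt(cr3$CR, 0.1)
  expect_true(cr3$flagged)
  expect_error(consistency_ratio(pairwise_matrix(matrix(1, 2, 2))), "3 <= n")
})

test_that("survey aggregation is the reciprocal geometric mean", {
  set.seed(2)
  mk <- function() {
    m <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    for (i in 1:3) for (j in (i + 1):4) {
      m[i, j] <- min(max(exp(rnorm(1)), 1 / 9), 9); m[j, i] <- 1 / m[i, j]
    }
    pairwise_matrix(m)
  }
  one <- mk()
  expect_equal(unclass(aggregate_surveys(list(one))), unclass(one),
               tolerance = 1e-12, ignore_attr = TRUE)

  ms <- replicate(12, mk(), simplify = FALSE)
  agg <- aggregate_surveys(ms)
  expect_lt(max(abs(unclass(agg) * t(unclass(agg)) - 1)), 1e-12)
  # oracle from logs
  oracle <- exp(Reduce(`+`, lapply(ms, function(m) log(unclass(m)))) / 12)
  expect_equal(unclass(agg), oracle, tolerance = 1e-9, ignore_attr = TRUE)
  # aggregate weights equal weights of the log-mean matrix
  expect_equal(unname(principal_weights(agg)$weights),
               unname(principal_weights(pairwise_matrix(oracle, letters[1:4]))$weights),
               tolerance = 1e-9)

  two <- mk(); rownames(two) <- colnames(two) <- c("a", "b", "c", "x")
  expect_error(aggregate_surveys(list(one, two)), "label mismatch")
})

test_that("AHP surface: degenerate weight configurations behave exactly", {
  land <- default_land()
  stack <- land$stacks$spring
  tm <- land$truth$spring
  # all category scores 1 -> suitability 1 everywhere
  tm_one <- tm
  tm_one$category_scores <- lapply(tm$category_scores, function(s) {
    s[] <- 1; s
  })
  s1 <- ahp_suitability(stack, tm_one)
  expect_equal(range(valid_values(s1)), c(1, 1))

  # a single variable with weight 1 reproduces that variable's scores
  tm_single <- tm
  tm_single$variable_weights[] <- 0
  tm_single$variable_weights["landcover"] <- 1
  s2 <- ahp_suitability(stack, tm_single)
  lc_scores <- tm$category_scores$landcover
  expect_equal(valid_values(s2),
               unname(lc_scores[as.character(valid_values(stack$layers$landcover))]))

  # missing category score errors
  tm_bad <- tm
  tm_bad$category_scores$landcover <-
    tm_bad$category_scores$landcover[-1]
  expect_error(ahp_suitability(stack, tm_bad), "unmapped")
})

test_that("invert_rescale maps [0,1] onto [r_min, 1] and reverses ranks", {
  set.seed(6)
  sp <- grid_spec(5, 5, 30)
  s <- raster_layer(matrix(runif(25), 5, 5), sp)
  s$values[1, 1] <- 1; s$values[5, 5] <- 0
  cost <- invert_rescale(s)
  expect_equal(cost$values[1, 1], 0.01)
  expect_equal(cost$values[5, 5], 1)
  expect_equal(rank(-valid_values(s)), rank(valid_values(cost)))
  expect_error(invert_rescale(raster_layer(matrix(0.4, 5, 5), sp)),
               "degenerate|constant")
})

test_that("synthetic surveys aggregate near the generating weights", {
  tm <- truth_model("spring")
  surveys <- gen_expert_surveys(tm, n_experts = 12, noise_sd = 0.15, seed = 3)
  expect_length(surveys, 12)
  w <- surveys_to_weights(surveys, tm$bin_edges)
  expect_equal(sum(w$variable_weights), 1, tolerance = 1e-9)
  # Table-2 structural property: contributions (weights x 100) sum to 100
  expect_equal(sum(100 * w$variable_weights), 100, tolerance = 1e-9)
  # NDVI-dominant truth: aggregated expert weights keep NDVI on top
  expect_equal(names(which.max(w$variable_weights)), "ndvi")
  # round-trip through the structured-text survey format
  f <- withr::local_tempfile(fileext = ".json")
  write_surveys_json(surveys, f)
  back <- read_surveys_json(f)
  expect_equal(unclass(back[[3]]$variables), unclass(surveys[[3]]$variables),
               tolerance = 1e-12, ignore_attr = TRUE)
  w2 <- surveys_to_weights(back, tm$bin_edges)
  expect_equal(w2$variable_weights, w$variable_weights, tolerance = 1e-9)
})
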