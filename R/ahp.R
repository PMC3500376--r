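# Expert-based habitat suitability by the Analytic Hierarchy Process:
# reciprocal pairwise judgment matrices on the 1-9 scale, principal
# eigenvector weights, Saaty consistency diagnostics, geometric-mean
# aggregation across experts, and a weighted-linear-combination surface.

#' Validate a pairwise comparison matrix
#'
#' @param m square positive matrix with unit diagonal, reciprocal within
#'   1e-9, entries in `[1/9, 9]`.
#' @param labels optional item labels.
#' @return the matrix with class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(m, labels = rownames(m)) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (ncol(m) != n) stop("pairwise matrix must be square")
  if (any(m <= 0)) stop("pairwise entries must be positive")
  if (any(abs(diag(m) - 1) > 1e-9)) stop("diagonal must be 1")
  if (max(abs(m * t(m) - 1)) > 1e-6)
    stop("matrix is not reciprocal (a_ji != 1/a_ij)")
  if (any(m > 9 + 1e-9) || any(m < 1 / 9 - 1e-9))
    stop("entries outside the 1-9 judgment scale")
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  dimnames(m) <- list(labels, labels)
  class(m) <- c("pairwise_matrix", "matrix")
  m
}

#' Principal-eigenvector weights of a pairwise matrix
#'
#' Power iteration to tolerance 1e-10; weights are the normalized principal
#' right eigenvector, `lambda_max` its eigenvalue.
#'
#' @param m a [pairwise_matrix()].
#' @return list with `weights` (sum 1) and `lambda_max`.
#' @export
principal_weights <- function(m) {
  m <- pairwise_matrix(unclass(m), rownames(m))
  n <- nrow(m)
  w <- rep(1 / n, n)
  for (it in 1:1000) {
    w2 <- as.numeric(m %*% w)
    w2 <- w2 / sum(w2)
    if (max(abs(w2 - w)) < 1e-10) { w <- w2; break }
    w <- w2
  }
  lambda_max <- mean((m %*% w) / w)
  list(weights = stats::setNames(w, rownames(m)), lambda_max = lambda_max)
}

# Saaty random consistency indices, n = 3..10
AHP_RI <- c(`3` = 0.58, `4` = 0.90, `5` = 1.12, `6` = 1.24, `7` = 1.32,
            `8` = 1.41, `9` = 1.45, `10` = 1.49)

#' Consistency ratio of a pairwise matrix
#'
#' `CI = (lambda_max - n)/(n - 1)`; `CR = CI / RI(n)` with the standard
#' random-index table. `CR > 0.1` conventionally flags intransitive
#' judgments; the flag is a warning, not a rejection.
#'
#' @param m a [pairwise_matrix()] with 3 <= n <= 10.
#' @param warn emit a warning when CR > 0.1 (default TRUE).
#' @return list with `CI`, `CR`, `lambda_max`, `flagged`.
#' @export
consistency_ratio <- function(m, warn = TRUE) {
  n <- nrow(m)
  if (!as.character(n) %in% names(AHP_RI))
    stop("consistency ratio defined for 3 <= n <= 10")
  pw <- principal_weights(m)
  CI <- (pw$lambda_max - n) / (n - 1)
  CR <- CI / AHP_RI[[as.character(n)]]
  flagged <- CR > 0.1
  if (flagged && warn)
    warning(sprintf("consistency ratio %.3f exceeds 0.1", CR))
  list(CI = CI, CR = CR, lambda_max = pw$lambda_max, flagged = flagged)
}

#' Aggregate expert surveys by element-wise geometric mean
#'
#' Aggregation of individual judgments (AIJ); the geometric mean of
#' reciprocal matrices is reciprocal by construction.
#'
#' @param matrices list of [pairwise_matrix()] with identical labels.
#' @return a [pairwise_matrix()].
#' @export
aggregate_surveys <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  lab <- rownames(matrices[[1]])
  for (m in matrices)
    if (!identical(rownames(m), lab)) stop("survey label mismatch")
  logs <- lapply(matrices, function(m) log(unclass(m)))
  agg <- exp(Reduce(`+`, logs) / length(logs))
  # snap tiny float asymmetry so the reciprocity check passes exactly
  agg[lower.tri(agg)] <- 1 / t(agg)[lower.tri(agg)]
  diag(agg) <- 1
  pairwise_matrix(agg, lab)
}

#' Expert weight set for the seven-variable suitability model
#'
#' @param variable_matrix 7x7 [pairwise_matrix()] over the covariate roles.
#' @param category_matrices named list (per role with >= 2 categories) of
#'   category-level pairwise matrices; category weights are rescaled so the
#'   best category of each variable scores 1.
#' @param bin_edges named list of bin edges for the continuous covariates
#'   (used to categorize them before scoring).
#' @param warn_cr warn on CR > 0.1.
#' @return object of class `ahp_weights` with `variable_weights`,
#'   `category_scores`, `bin_edges`, `diagnostics` (per-matrix lambda_max,
#'   CI, CR).
#' @export
ahp_weights <- function(variable_matrix, category_matrices, bin_edges,
                        warn_cr = FALSE) {
  vw <- principal_weights(variable_matrix)
  diag_rows <- list()
  add_diag <- function(name, m) {
    if (nrow(m) < 3) {
      # a reciprocal 2x2 matrix is always consistent; CR is undefined there
      diag_rows[[name]] <<- data.frame(matrix = name,
                                       lambda_max = nrow(m), CI = 0,
                                       CR = NA_real_, flagged = FALSE)
      return(invisible())
    }
    cr <- consistency_ratio(m, warn = warn_cr)
    diag_rows[[name]] <<- data.frame(matrix = name, lambda_max = cr$lambda_max,
                                     CI = cr$CI, CR = cr$CR,
                                     flagged = cr$flagged)
  }
  add_diag("variables", variable_matrix)
  scores <- list()
  for (nm in names(category_matrices)) {
    cm <- category_matrices[[nm]]
    cw <- principal_weights(cm)$weights
    scores[[nm]] <- cw / max(cw)         # best category scores 1
    add_diag(nm, cm)
  }
  structure(list(variable_weights = vw$weights, category_scores = scores,
                 bin_edges = bin_edges,
                 diagnostics = do.call(rbind, unname(diag_rows))),
            class = "ahp_weights")
}

# Categorize every layer of a stack into integer codes using the weight
# set's bin edges (continuous) or the codes themselves (categorical/binary).
categorize_stack <- function(stack, weights) {
  out <- list()
  for (role in names(stack$layers)) {
    layer <- stack$layers[[role]]
    if (layer$kind == "continuous") {
      edges <- weights$bin_edges[[role]]
      if (is.null(edges)) stop("no bin edges for continuous variable ", role)
      out[[role]] <- reclassify(layer, list(edges = edges))
    } else {
      out[[role]] <- layer
    }
  }
  out
}

#' Expert-weighted suitability surface
#'
#' `suitability(cell) = sum_v w_v * s_v(category_v(cell))`: continuous
#' covariates are binned on the weight set's edges, every covariate's
#' category is looked up in its score table (error if a category has no
#' score), and scores are combined with the variable weights. Lies in
#' `[0, 1]` because weights sum to 1 and the best category of each
#' variable scores 1.
#'
#' @param stack a [covariate_stack()].
#' @param weights an [ahp_weights()] (or [truth_model()], which shares the
#'   same scoring definition).
#' @return continuous [raster_layer()] in `[0, 1]`.
#' @export
ahp_suitability <- function(stack, weights) {
  w <- weights$variable_weights
  if (!setequal(names(w), names(stack$layers)))
    stop("weights must cover all seven covariates")
  cat_layers <- categorize_stack(stack, weights)
  acc <- matrix(0, stack$spec$nrows, stack$spec$ncols)
  ok <- matrix(TRUE, stack$spec$nrows, stack$spec$ncols)
  for (role in names(cat_layers)) {
    scores <- weights$category_scores[[role]]
    if (is.null(scores)) stop("no category scores for variable ", role)
    scored <- reclassify(cat_layers[[role]], list(map = scores))
    ok <- ok & !is.na(scored$values)
    acc <- acc + w[[role]] * ifelse(is.na(scored$values), 0, scored$values)
  }
  acc[!ok] <- NA_real_
  raster_layer(acc, stack$spec, "continuous")
}

#' Invert a suitability surface into a cost surface
#'
#' `cost = 1 - suitability`, mapped affinely from `[0, 1]` onto
#' `[r_min, 1]` so the best habitat costs `r_min` (> 0) and the worst
#' costs 1.
#'
#' @param layer continuous [raster_layer()] in `[0, 1]`.
#' @param r_min minimum cost, default 0.01 (shared with
#'   [suitability_to_resistance()]).
#' @return continuous [raster_layer()] in `[r_min, 1]`.
#' @export
invert_rescale <- function(layer, r_min = 0.01) {
  v <- valid_values(layer)
  if (any(v < -1e-9 | v > 1 + 1e-9)) stop("suitability must lie in [0, 1]")
  if (diff(range(v)) == 0) stop("degenerate (constant) suitability layer")
  raster_layer(r_min + (1 - r_min) * (1 - layer$values), layer$spec,
               "continuous")
}

#' Generate synthetic expert surveys around a truth model
#'
#' Builds near-consistent pairwise matrices whose ratios track the truth
#' model's variable weights and category scores, perturbed by lognormal
#' judgment noise and clamped to the 1-9 scale. Consumed by
#' [aggregate_surveys()] / [ahp_weights()] exactly like field surveys.
#'
#' @param truth a [truth_model()].
#' @param n_experts number of surveys (the study received 11-12).
#' @param noise_sd sd of the log-judgment noise.
#' @param seed integer seed.
#' @return list of surveys; each has `variables` (7x7) and `categories`
#'   (named list of per-variable matrices).
#' @export
gen_expert_surveys <- function(truth, n_experts = 12, noise_sd = 0.15,
                               seed = 1) {
  mk <- function(w) {
    n <- length(w)
    m <- matrix(1, n, n, dimnames = list(names(w), names(w)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- (w[i] / w[j]) * exp(stats::rnorm(1, 0, noise_sd))
        r <- min(max(r, 1 / 9), 9)
        m[i, j] <- r; m[j, i] <- 1 / r
      }
    }
    pairwise_matrix(m)
  }
  with_seed(seed, {
    lapply(seq_len(n_experts), function(e) {
      list(variables = mk(truth$variable_weights),
           categories = lapply(truth$category_scores, function(s)
             if (length(s) >= 2) mk(s) else NULL))
    })
  })
}

#' Aggregate surveys into one expert weight set
#'
#' @param surveys list from [gen_expert_surveys()] (or parsed field
#'   surveys of the same shape).
#' @param bin_edges bin edges for the continuous covariates.
#' @return an [ahp_weights()].
#' @export
surveys_to_weights <- function(surveys, bin_edges) {
  var_m <- aggregate_surveys(lapply(surveys, `[[`, "variables"))
  roles <- names(surveys[[1]]$categories)
  cat_m <- list()
  for (role in roles) {
    ms <- lapply(surveys, function(s) s$categories[[role]])
    ms <- ms[!vapply(ms, is.null, logical(1))]
    if (length(ms)) cat_m[[role]] <- aggregate_surveys(ms)
  }
  ahp_weights(var_m, cat_m, bin_edges)
}

#' Write / read surveys as structured text (JSON)
#' @param surveys list of surveys.
#' @param path file path.
#' @return `path` invisibly (write); survey list (read).
#' @export
write_surveys_json <- function(surveys, path) {
  ser_m <- function(m) list(labels = rownames(m),
                            rows = apply(unclass(m), 1, as.list,
                                         simplify = FALSE))
  ser <- lapply(surveys, function(s) list(
    variables = ser_m(s$variables),
    categories = lapply(Filter(Negate(is.null), s$categories), ser_m)))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surveys_json
#' @export
read_surveys_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_m <- function(x) {
    m <- do.call(rbind, lapply(x$rows, function(r) as.numeric(unlist(r))))
    pairwise_matrix(m, unlist(x$labels))
  }
  lapply(raw, function(s) list(
    variables = de_m(s$variables),
    categories = lapply(s$categories, de_m)))
}
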