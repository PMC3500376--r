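# Presence-only maximum-entropy habitat model, written from first
# principles. The model puts a Gibbs distribution q(cell) ~ exp(lambda . f)
# over background cells and chooses lambda to maximize the L1-regularized
# average log-density of the presence cells:
#   J(lambda) = lambda . mean_f(presences) - log Z - sum_j beta_j |lambda_j|
# by cyclic coordinate ascent with a monotonicity safeguard. At convergence
# the KKT conditions give the classic box constraints
# |E_q[f_j] - E_presence[f_j]| <= beta_j. Features are linear + quadratic
# terms of standardized continuous covariates plus one indicator per
# category of categorical covariates (no hinge/threshold features).

#' Build the feature matrix for a covariate stack
#'
#' Continuous covariates contribute standardized linear and quadratic
#' columns (both centered/scaled over all valid cells); categorical and
#' binary covariates contribute one 0/1 indicator per observed category.
#' Feature order is deterministic (roles in stack order, categories in code
#' order).
#'
#' @param stack a [covariate_stack()].
#' @param exclude character vector of roles to drop (default `"dist_wells"`,
#'   excluded from the presence-only model because collaring occurred inside
#'   the gas field).
#' @return object of class `feature_matrix`: list with `X` (cells x
#'   features), `feature_names`, `variable` (owning covariate per feature),
#'   `cells` (column-major linear index of each row), `spec`.
#' @export
build_features <- function(stack, exclude = "dist_wells") {
  roles <- setdiff(names(stack$layers), exclude)
  ok <- Reduce(`&`, lapply(stack$layers[roles], valid_mask))
  cells <- which(ok)
  cols <- list(); vars <- character(0)
  for (role in roles) {
    layer <- stack$layers[[role]]
    v <- layer$values[cells]
    if (all(is.na(v))) stop("covariate ", role, " is all nodata")
    if (layer$kind == "continuous") {
      if (stats::sd(v) == 0) stop("zero variance covariate: ", role)
      z <- as.numeric(scale(v))
      z2 <- as.numeric(scale(z^2))
      if (any(!is.finite(z2))) z2 <- rep(0, length(z))
      cols[[paste0(role, ":lin")]] <- z
      cols[[paste0(role, ":quad")]] <- z2
      vars <- c(vars, role, role)
    } else {
      codes <- sort(unique(v))
      if (length(codes) < 2 && layer$kind == "categorical")
        stop("zero variance covariate: ", role)
      for (cd in codes) {
        cols[[paste0(role, ":cat", cd)]] <- as.numeric(v == cd)
        vars <- c(vars, role)
      }
    }
  }
  X <- do.call(cbind, cols)
  structure(list(X = X, feature_names = colnames(X), variable = vars,
                 cells = cells, spec = stack$spec),
            class = "feature_matrix")
}

rows_for_cells <- function(features, cells) {
  idx <- match(cells, features$cells)
  if (anyNA(idx)) stop("some cells are outside the valid feature universe")
  idx
}

#' Fit the maximum-entropy model
#'
#' @param features a [build_features()] result.
#' @param presence_cells column-major linear cell indices of presences
#'   (>= 20 after deduplication, if any, is recommended upstream).
#' @param background_cells linear cell indices of the background sample; use
#'   [sample_background()] for the default seeded uniform sample.
#' @param beta non-negative regularization multiplier (default 0.5). The
#'   per-feature L1 weight is `beta * sd_j(background) / sqrt(m)` with `m`
#'   the presence count -- the usual presence-only scaling, under which the
#'   penalty matches the sampling noise of the presence feature means
#'   instead of swamping it. A vector of length `ncol(X)` is taken as
#'   absolute per-feature weights instead.
#' @param opts list: `tol` (objective change per sweep, default 1e-8),
#'   `maxit` (single-feature updates, default 20000).
#' @return object of class `maxent_model`: `lambda`, `log_z` (log partition
#'   over the background sample), `beta`, entropy `H` of the fitted
#'   distribution, `gain_trace` (per-update objective gains by feature),
#'   `objective`, convergence metadata.
#' @export
fit_maxent <- function(features, presence_cells, background_cells, beta = 0.5,
                       opts = list()) {
  o <- utils::modifyList(list(tol = 1e-8, maxit = 20000), opts)
  if (length(presence_cells) < 20) stop("need at least 20 presence cells")
  Xp <- features$X[rows_for_cells(features, presence_cells), , drop = FALSE]
  Xb <- features$X[rows_for_cells(features, background_cells), , drop = FALSE]
  p <- ncol(Xb); nb <- nrow(Xb)
  if (length(beta) == 1) {
    sds <- apply(Xb, 2, stats::sd)
    beta <- beta * sds / sqrt(nrow(Xp))
  } else if (length(beta) != p) {
    stop("beta must be a scalar multiplier or one weight per feature")
  }
  fbar <- colMeans(Xp)

  lambda <- numeric(p)
  eta <- numeric(nb)
  logZ <- 0                     # log mean exp(eta); starts at log(1)
  obj <- function(lmb, lZ) sum(lmb * fbar) - lZ - sum(beta * abs(lmb))
  J <- obj(lambda, logZ)
  gains <- list()
  converged <- FALSE
  Xb2 <- Xb * Xb
  for (it in seq_len(o$maxit)) {
    # greedy coordinate selection (the sequential-update algorithm): score
    # every feature's prox step by its quadratic gain model, update the best
    w <- exp(eta - max(eta)); w <- w / sum(w)
    mu <- as.numeric(crossprod(Xb, w))
    v <- pmax(as.numeric(crossprod(Xb2, w)) - mu^2, 0)
    g <- fbar - mu
    usable <- v > 1e-12
    z <- lambda + ifelse(usable, g / pmax(v, 1e-12), 0)
    lnew <- sign(z) * pmax(abs(z) - beta / pmax(v, 1e-12), 0)
    step <- ifelse(usable, lnew - lambda, 0)
    est <- g * step - v * step^2 / 2 - beta * (abs(lambda + step) - abs(lambda))
    est[!usable] <- -Inf
    # convergence: KKT box constraints met and no worthwhile step remains
    kkt <- abs(g) - beta
    if (max(kkt) <= 1e-8 && max(est) < o$tol) { converged <- TRUE; break }
    j <- which.max(est)
    if (step[j] == 0) { converged <- max(kkt) <= 1e-8; break }
    # monotone safeguard: damp toward the old value until J does not drop
    s <- step[j]
    repeat {
      cand <- lambda[j] + s
      eta_c <- eta + s * Xb[, j]
      m <- max(eta_c)
      logZ_c <- m + log(mean(exp(eta_c - m)))
      lmb_c <- lambda; lmb_c[j] <- cand
      J_c <- obj(lmb_c, logZ_c)
      if (J_c >= J - 1e-12 || abs(s) < 1e-14) break
      s <- s / 2
    }
    if (J_c >= J - 1e-12) {      # accept; 1e-12 absorbs float noise near KKT
      if (J_c > J)
        gains[[length(gains) + 1]] <- c(feature = j, gain = J_c - J)
      lambda[j] <- cand; eta <- eta_c; logZ <- logZ_c; J <- J_c
    } else break                 # no acceptable step; KKT checked above
  }
  if (!converged)
    stop(sprintf("maxent did not converge in %d iterations (last objective %.8g)",
                 o$maxit, J))
  w <- exp(eta - logZ) / nb     # q over background, sums to 1
  H <- -sum(w * log(pmax(w, 1e-300)))
  gt <- if (length(gains)) as.data.frame(do.call(rbind, gains)) else
    data.frame(feature = integer(0), gain = numeric(0))
  structure(list(lambda = stats::setNames(lambda, features$feature_names),
                 log_z = logZ, beta = stats::setNames(beta, features$feature_names),
                 H = H, objective = J, iterations = it, gain_trace = gt,
                 feature_names = features$feature_names,
                 variable = features$variable,
                 n_presence = length(presence_cells),
                 n_background = nb,
                 background_cells = background_cells),
            class = "maxent_model")
}

#' @exportS3Method base::print
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model: %d features, %d presences, %d background, objective %.6g (%d iterations)>\n",
              length(x$lambda), x$n_presence, x$n_background, x$objective,
              x$iterations))
}

#' Seeded uniform background sample
#' @param features a [build_features()] result.
#' @param n sample size (default 10000, capped at the number of valid cells).
#' @param seed integer seed.
#' @return vector of linear cell indices.
#' @export
sample_background <- function(features, n = 10000, seed = 1) {
  cells <- features$cells
  if (length(cells) <= n) return(cells)
  with_seed(seed, sort(sample(cells, n)))
}

#' Predict from a fitted maxent model
#'
#' Modes: `"raw"` is the Gibbs density q per cell, normalized to sum to 1
#' over the model's background sample; `"log"` is its natural log;
#' `"logistic"` rescales onto `[0, 1]` as `plogis(H + log q)` with `H` the
#' entropy of q, so the uniform (lambda = 0) model scores 0.5 everywhere.
#'
#' @param object a `maxent_model`.
#' @param features a [build_features()] result on the same stack layout.
#' @param mode `"raw"`, `"log"` or `"logistic"`.
#' @param ... unused.
#' @return continuous [raster_layer()].
#' @export
predict.maxent_model <- function(object, features, mode = c("logistic", "raw", "log"),
                                 ...) {
  mode <- match.arg(mode)
  if (!identical(object$feature_names, features$feature_names))
    stop("feature matrix does not match the fitted model")
  eta <- as.numeric(features$X %*% object$lambda)
  lograw <- eta - object$log_z - log(object$n_background)
  vals <- switch(mode,
                 raw = exp(lograw),
                 log = lograw,
                 logistic = stats::plogis(object$H + lograw))
  sp <- features$spec
  m <- matrix(NA_real_, sp$nrows, sp$ncols)
  m[features$cells] <- vals
  raster_layer(m, sp, "continuous")
}

#' Random train/test split of presence points
#'
#' @param points data.frame (or vector of cell indices).
#' @param test_frac held-back fraction (default 0.25).
#' @param seed integer seed.
#' @return list with `train` and `test` subsets (disjoint, exhaustive).
#' @export
split_points <- function(points, test_frac = 0.25, seed = 1) {
  n <- if (is.data.frame(points)) nrow(points) else length(points)
  if (n < 8) stop("need at least 8 points to split")
  n_test <- floor(n * test_frac + 0.5)
  idx <- with_seed(seed, sample(n, n_test))
  take <- function(sel) if (is.data.frame(points)) points[sel, , drop = FALSE]
                        else points[sel]
  sel <- logical(n); sel[idx] <- TRUE
  list(train = take(!sel), test = take(sel))
}

#' Presence-background AUC (Mann-Whitney)
#'
#' `P(score_presence > score_background) + 0.5 P(tie)`, computed from ranks.
#'
#' @param presence_scores,background_scores numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_presence_background <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  m <- length(presence_scores); n <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Per-variable percent contributions
#'
#' Credits each coordinate-ascent update's objective gain to the covariate
#' owning the updated feature and normalizes the per-variable totals to
#' 100%.
#'
#' @param model a fitted `maxent_model`.
#' @return named numeric vector of percentages summing to 100.
#' @export
variable_contributions <- function(model) {
  if (nrow(model$gain_trace) == 0) stop("model carries no fit trace")
  per_feat <- tapply(model$gain_trace$gain, model$gain_trace$feature, sum)
  contrib <- stats::setNames(numeric(length(unique(model$variable))),
                             unique(model$variable))
  for (k in seq_along(per_feat)) {
    v <- model$variable[as.integer(names(per_feat)[k])]
    contrib[v] <- contrib[v] + per_feat[k]
  }
  contrib <- pmax(contrib, 0)
  100 * contrib / sum(contrib)
}

#' Jackknife variable importance
#'
#' Refits the model with each covariate alone and with each covariate
#' withheld; gains are the regularized training objective above the null
#' (lambda = 0) model, which scores 0.
#'
#' @param stack a [covariate_stack()].
#' @param presence_cells,background_cells as in [fit_maxent()].
#' @param exclude roles excluded from the full model.
#' @param beta,opts passed to [fit_maxent()].
#' @return data.frame with `variable`, `gain_only`, `gain_without`.
#' @export
jackknife <- function(stack, presence_cells, background_cells,
                      exclude = "dist_wells", beta = 0.5, opts = list()) {
  roles <- setdiff(names(stack$layers), exclude)
  fit_gain <- function(excl) {
    f <- build_features(stack, exclude = excl)
    m <- fit_maxent(f, presence_cells, background_cells, beta, opts)
    m$objective
  }
  out <- data.frame(variable = roles, gain_only = NA_real_,
                    gain_without = NA_real_)
  for (i in seq_along(roles)) {
    out$gain_only[i] <- fit_gain(union(exclude, setdiff(roles, roles[i])))
    out$gain_without[i] <- fit_gain(union(exclude, roles[i]))
  }
  out
}

#' Convert a suitability surface into a movement resistance surface
#'
#' For the maxent path the raw output is floored at `1e-12`, log
#' transformed, rescaled onto `[0, 1]` over its observed range and
#' inverted; the inverted surface is mapped affinely onto
#' `[r_min, 1]` (`r_min = 0.01`) so costs stay strictly positive for the
#' graph algorithms. Rank order is exactly reversed relative to
#' suitability.
#'
#' @param layer continuous [raster_layer()] (strictly positive raw maxent
#'   output for `mode = "maxent"`; a `[0, 1]` suitability for
#'   `mode = "linear"`).
#' @param mode `"maxent"` (log transform first) or `"linear"`.
#' @param r_min minimum resistance (default 0.01).
#' @return continuous [raster_layer()] in `[r_min, 1]`.
#' @export
suitability_to_resistance <- function(layer, mode = c("maxent", "linear"),
                                      r_min = 0.01) {
  mode <- match.arg(mode)
  v <- valid_values(layer)
  if (diff(range(v)) == 0) stop("degenerate (constant) suitability layer")
  if (mode == "maxent") {
    logl <- raster_layer(log(pmax(layer$values, 1e-12)), layer$spec,
                         "continuous")
    r <- rescale01(logl)
    vals <- r_min + (1 - r_min) * (1 - r$values)
  } else {
    vals <- r_min + (1 - r_min) * (1 - layer$values)
  }
  raster_layer(vals, layer$spec, "continuous")
}
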