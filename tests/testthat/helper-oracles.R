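# Independent oracles and shared fixtures. The oracles deliberately avoid
# every code path they check: shortest paths by Bellman-Ford relaxation on
# an explicit edge list, circuit voltages by a dense base-R solve, distances
# by exhaustive min-over-features.

# Explicit 8-neighbour edge list of a cost grid (linear indices, column-major)
grid_edge_list <- function(cost, cellsize) {
  nr <- nrow(cost); nc <- ncol(cost)
  edges <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(cost[r, c])) next
      a <- r + (c - 1) * nr
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (is.na(cost[rr, cc])) next
        b <- rr + (cc - 1) * nr
        d <- cellsize * if (dr != 0 && dc != 0) sqrt(2) else 1
        edges[[length(edges) + 1]] <-
          c(a, b, 0.5 * (cost[r, c] + cost[rr, cc]) * d)
      }
    }
  }
  do.call(rbind, edges)
}

# Bellman-Ford multi-source shortest distances (iterate to fixpoint)
bf_cost_distance <- function(cost, sources_lin, cellsize) {
  n <- length(cost)
  e <- grid_edge_list(cost, cellsize)
  d <- rep(Inf, n)
  d[sources_lin] <- 0
  repeat {
    nd <- pmin(d, suppressWarnings(
      tapply(d[e[, 1]] + e[, 3], e[, 2], min)[as.character(seq_len(n))]),
      na.rm = TRUE)
    nd[is.na(nd)] <- Inf
    nd <- pmin(d, nd)
    if (all(nd == d | (is.infinite(nd) & is.infinite(d)))) break
    d <- nd
  }
  d
}

# Dense circuit solve: single-cell focal nodes, no contraction
dense_circuit_voltages <- function(resistance, src_lin, dst_lin, cellsize) {
  n <- length(resistance)
  e <- grid_edge_list(resistance, cellsize)
  g <- 1 / e[, 3]                 # conductance = 1 / (mean resistance * d)
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(e))) {
    # the edge list holds both directed appearances of every undirected
    # edge; each appearance fills its own row of the Laplacian
    a <- e[k, 1]; b <- e[k, 2]
    L[a, b] <- L[a, b] - g[k]
    L[a, a] <- L[a, a] + g[k]
  }
  keep <- setdiff(which(!is.na(resistance)), dst_lin)
  bvec <- numeric(n); bvec[src_lin] <- 1
  v <- numeric(n)
  v[keep] <- solve(L[keep, keep], bvec[keep])
  v
}

# Random strictly positive cost grid
random_cost_grid <- function(nr, nc, cellsize = 30, seed = 1) {
  set.seed(seed)
  raster_layer(matrix(runif(nr * nc, 0.05, 1), nr, nc),
               grid_spec(nr, nc, cellsize))
}

# Cached default landscape/telemetry (shared by the heavier tests)
.fixture_cache <- new.env(parent = emptyenv())

default_land <- function() {
  if (is.null(.fixture_cache$land))
    .fixture_cache$land <- gen_landscape(landscape_params(seed = 1))
  .fixture_cache$land
}

default_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- gen_tracks(default_land(), telemetry_params(seed = 1))
  .fixture_cache$sim
}

small_pipeline_config <- function(seed = 11) {
  cfg <- default_config(seed)
  cfg$landscape <- list(nrows = 60, ncols = 60, cellsize = 1800)
  cfg$telemetry <- list(n_individuals = 14, spring_migrants = 5,
                        fall_migrants = 6, fix_interval_h = 4)
  cfg$hsm$background_n <- 3000
  cfg
}
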