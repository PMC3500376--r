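# Circuit-theory connectivity. The resistance raster becomes an electrical
# network: valid cells are nodes, 8-neighbour edges carry conductance
# g = 1 / (mean(r_a, r_b) * d) -- the same endpoint-mean edge rule as the
# least-cost graph, so the two engines see commensurate landscapes. Focal
# habitat patches are contracted to supernodes (zero internal resistance).
# Grounding one focal node and injecting unit current at the other turns
# Kirchhoff's laws into a sparse reduced-Laplacian solve; per-edge currents
# follow from Ohm's law, effective resistance from the source voltage.

#' Build a circuit network from a resistance raster
#'
#' @param resistance continuous [raster_layer()] with values >= r_min > 0.
#' @param focal_regions list of cell sets ((row, col) matrices or linear
#'   indices); each region is contracted to a single supernode. Must be
#'   disjoint and inside the valid mask.
#' @param neighbourhood 8 (default) or 4.
#' @return object of class `circuit_network`: `nodes` (supernode count +
#'   free cells), `edges` (data.frame a, b, conductance), `node_of_cell`
#'   (linear cell index -> node id), `focal_nodes`, `spec`, `components`.
#' @export
build_network <- function(resistance, focal_regions, neighbourhood = 8) {
  check_costs(resistance)
  sp <- resistance$spec
  vals <- resistance$values
  nr <- sp$nrows; nc <- sp$ncols
  nf <- length(focal_regions)
  node_of_cell <- rep(NA_integer_, nr * nc)
  valid <- !is.na(vals)
  seen <- integer(0)
  for (k in seq_len(nf)) {
    lin <- cells_to_linear(sp, focal_regions[[k]])
    if (any(!valid[lin])) stop("focal region ", k, " outside valid mask")
    if (any(lin %in% seen)) stop("focal regions must be disjoint")
    seen <- c(seen, lin)
    node_of_cell[lin] <- k
  }
  free <- which(valid & is.na(node_of_cell))
  node_of_cell[free] <- nf + seq_along(free)
  n_nodes <- nf + length(free)

  # enumerate undirected neighbour pairs once (right, down, and diagonals)
  offs <- list(c(0, 1), c(1, 0))
  if (neighbourhood == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  ea <- integer(0); eb <- integer(0); eg <- numeric(0)
  cell_r <- integer(0); cell_c <- integer(0)
  from_cell <- integer(0); to_cell <- integer(0)
  for (off in offs) {
    dr <- off[1]; dc <- off[2]
    r0 <- seq_len(nr - dr)
    c0 <- if (dc >= 0) seq_len(nc - dc) else (1 - dc):nc
    rr <- rep(r0, times = length(c0)); cc <- rep(c0, each = length(r0))
    a <- rr + (cc - 1L) * nr
    b <- (rr + dr) + (cc + dc - 1L) * nr
    keep <- valid[a] & valid[b]
    a <- a[keep]; b <- b[keep]
    d <- sp$cellsize * if (dr != 0 && dc != 0) sqrt(2) else 1
    g <- 1 / (0.5 * (vals[a] + vals[b]) * d)
    ea <- c(ea, node_of_cell[a]); eb <- c(eb, node_of_cell[b])
    eg <- c(eg, g)
    from_cell <- c(from_cell, a); to_cell <- c(to_cell, b)
  }
  # drop edges internal to one supernode; keep parallel edges (they add)
  keep <- ea != eb
  edges <- data.frame(a = ea[keep], b = eb[keep], g = eg[keep],
                      cell_a = from_cell[keep], cell_b = to_cell[keep])
  comp <- label_components(valid & !is.na(vals), as.integer(neighbourhood))
  structure(list(n_nodes = n_nodes, n_focal = nf, edges = edges,
                 node_of_cell = node_of_cell, spec = sp,
                 components = comp),
            class = "circuit_network")
}

#' @exportS3Method base::print
print.circuit_network <- function(x, ...) {
  cat(sprintf("<circuit_network: %d nodes (%d focal), %d edges>\n",
              x$n_nodes, x$n_focal, nrow(x$edges)))
}

network_laplacian <- function(network) {
  e <- network$edges
  n <- network$n_nodes
  Matrix::sparseMatrix(i = c(e$a, e$b, e$a, e$b),
                       j = c(e$b, e$a, e$a, e$b),
                       x = c(-e$g, -e$g, e$g, e$g),
                       dims = c(n, n))
}

#' Solve the pair problem: unit current between two focal nodes
#'
#' Grounds `dst`, injects one unit of current at `src`, solves the reduced
#' Laplacian system, and recovers per-edge currents by Ohm's law. The
#' source voltage is the effective resistance.
#'
#' @param network a [build_network()] result.
#' @param src,dst focal node ids (1-based, in focal-region order).
#' @return object of class `circuit_solution`: `voltages` (per node),
#'   `edge_currents`, `R_eff`, `src`, `dst`.
#' @export
solve_pair <- function(network, src, dst) {
  stopifnot(src != dst, src <= network$n_focal, dst <= network$n_focal)
  # connectivity check via edges (components of the contracted graph)
  L <- network_laplacian(network)
  n <- network$n_nodes
  keep <- setdiff(seq_len(n), dst)
  b <- numeric(n); b[src] <- 1
  Lr <- L[keep, keep, drop = FALSE]
  v <- tryCatch(as.numeric(Matrix::solve(Lr, b[keep])),
                error = function(e)
                  stop("singular system: focal nodes lie in disconnected ",
                       "components (infinite effective resistance)"))
  voltages <- numeric(n)
  voltages[keep] <- v
  if (!all(is.finite(voltages))) stop("singular system: disconnected focal pair")
  e <- network$edges
  ic <- (voltages[e$a] - voltages[e$b]) * e$g
  structure(list(voltages = voltages, edge_currents = ic,
                 R_eff = voltages[src], src = src, dst = dst,
                 injected = 1),
            class = "circuit_solution")
}

#' Per-cell current map of a solved network
#'
#' Each free cell carries half the sum of the absolute currents on its
#' incident edges (current in equals current out at interior nodes); cells
#' of the two active focal regions are assigned the injected current.
#'
#' @param network a [build_network()] result.
#' @param solution a [solve_pair()] result.
#' @return continuous non-negative [raster_layer()].
#' @export
current_map <- function(network, solution) {
  sp <- network$spec
  acc <- numeric(network$n_nodes)
  e <- network$edges
  a_abs <- abs(solution$edge_currents)
  acc_a <- tapply(a_abs, e$a, sum)
  acc_b <- tapply(a_abs, e$b, sum)
  acc[as.integer(names(acc_a))] <- acc[as.integer(names(acc_a))] + acc_a
  acc[as.integer(names(acc_b))] <- acc[as.integer(names(acc_b))] + acc_b
  acc <- acc / 2
  acc[c(solution$src, solution$dst)] <- solution$injected
  m <- matrix(NA_real_, sp$nrows, sp$ncols)
  has <- !is.na(network$node_of_cell)
  m[which(has)] <- acc[network$node_of_cell[has]]
  raster_layer(m, sp, "continuous")
}

#' Cumulative current map over focal-pair solves
#'
#' Sums the current maps of the requested ordered pairs (the seasonal
#' scheme: one source patch against each destination patch in turn; by
#' network reciprocity the direction of each pair does not matter).
#'
#' @param resistance continuous resistance [raster_layer()].
#' @param focal_regions list of cell sets (>= 2).
#' @param pairs two-column matrix of focal ids; default pairs region 1
#'   with every other region.
#' @param neighbourhood 8 or 4.
#' @return list with `current` (cumulative [raster_layer()]), `R_eff`
#'   (data.frame per pair), `network`.
#' @export
cumulative_current <- function(resistance, focal_regions, pairs = NULL,
                               neighbourhood = 8) {
  stopifnot(length(focal_regions) >= 2)
  if (is.null(pairs))
    pairs <- cbind(1, seq_along(focal_regions)[-1])
  network <- build_network(resistance, focal_regions, neighbourhood)
  total <- NULL
  reff <- list()
  for (k in seq_len(nrow(pairs))) {
    sol <- solve_pair(network, pairs[k, 1], pairs[k, 2])
    cm <- current_map(network, sol)
    total <- if (is.null(total)) cm$values else total + cm$values
    reff[[k]] <- data.frame(src = pairs[k, 1], dst = pairs[k, 2],
                            R_eff = sol$R_eff)
  }
  list(current = raster_layer(total, resistance$spec, "continuous"),
       R_eff = do.call(rbind, reff), network = network)
}

#' Slice a corridor mask from a current map
#'
#' Keeps the highest-current `p`% of valid cells (minimal superset, ties
#' included) and reports whether the first two focal regions are connected
#' through the mask (8-neighbour components) as attribute `connected`.
#'
#' @param current continuous [raster_layer()] (higher = more flow).
#' @param p threshold percentage in (0, 100].
#' @param focal_regions optional list of cell sets for the connectivity
#'   diagnostic.
#' @param provenance optional provenance list.
#' @return binary [raster_layer()] with attributes `provenance` and
#'   `connected`.
#' @export
slice_current <- function(current, p, focal_regions = NULL,
                          provenance = NULL) {
  stopifnot(p > 0, p <= 100)
  v <- current$values
  vv <- v[!is.na(v)]
  if (length(unique(vv)) == 1) stop("constant current map")
  thr <- sort(vv, decreasing = TRUE)[ceiling(p / 100 * length(vv))]
  mask <- ifelse(!is.na(v) & v >= thr, 1, 0)
  mask[is.na(v)] <- NA_real_
  out <- raster_layer(mask, current$spec, "binary")
  connected <- NA
  if (!is.null(focal_regions) && length(focal_regions) >= 2) {
    lab <- label_components(!is.na(mask) & mask == 1, 8L)
    l1 <- lab[as_cell_matrix(current$spec, focal_regions[[1]])]
    l2 <- lab[as_cell_matrix(current$spec, focal_regions[[2]])]
    connected <- length(intersect(setdiff(l1, 0), setdiff(l2, 0))) > 0
  }
  attr(out, "provenance") <- c(provenance,
                               list(threshold_pct = p, basis = "top_current",
                                    threshold_value = thr))
  attr(out, "connected") <- connected
  out
}
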