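test_that("network construction: strips, edge counts, disconnection", {
  strip <- raster_layer(matrix(1, 1, 3), grid_spec(1, 3, 1))
  net <- build_network(strip, list(cbind(1, 1), cbind(1, 3)))
  expect_equal(net$n_nodes, 3)               # 2 supernodes + 1 interior
  expect_equal(net$n_focal, 2)

  # 8-neighbourhood 3x3 full grid: 12 orthogonal + 8 diagonal = 20 edges
  full <- raster_layer(matrix(1, 3, 3), grid_spec(3, 3, 1))
  net2 <- build_network(full, list(), neighbourhood = 8)
  expect_equal(nrow(net2$edges), 20)

  # disconnected focal pair -> singular solve flagged
  m <- matrix(1, 3, 3); m[, 2] <- NA
  disc <- raster_layer(m, grid_spec(3, 3, 1))
  netd <- build_network(disc, list(cbind(1, 1), cbind(1, 3)))
  expect_error(solve_pair(netd, 1, 2), "singular|disconnected")

  m2 <- matrix(1, 3, 3); m2[2, 2] <- NA
  expect_error(build_network(raster_layer(m2, grid_spec(3, 3, 1)),
                             list(cbind(2, 2))), "outside valid mask")
})

test_that("series and parallel analytic limits", {
  # 1x3 strip, unit resistance, cellsize 1: two unit resistors in series
  strip <- raster_layer(matrix(1, 1, 3), grid_spec(1, 3, 1))
  net <- build_network(strip, list(cbind(1, 1), cbind(1, 3)))
  sol <- solve_pair(net, 1, 2)
  expect_equal(sol$R_eff, 2, tolerance = 1e-10)
  cm <- current_map(net, sol)
  expect_equal(cm$values[1, 2], 1, tolerance = 1e-10)  # full current through

  # two disjoint parallel paths of equal length halve the resistance
  m <- matrix(NA_real_, 3, 5)
  m[1, ] <- 1; m[3, ] <- 1; m[2, 1] <- 1; m[2, 5] <- 1
  twop <- raster_layer(m, grid_spec(3, 5, 1))
  net2 <- build_network(twop, list(cbind(2, 1), cbind(2, 5)))
  sol2 <- solve_pair(net2, 1, 2)
  one_m <- matrix(NA_real_, 3, 5); one_m[1, ] <- 1
  one_m[2, 1] <- 1; one_m[2, 5] <- 1
  net1 <- build_network(raster_layer(one_m, grid_spec(3, 5, 1)),
                        list(cbind(2, 1), cbind(2, 5)))
  sol1 <- solve_pair(net1, 1, 2)
  expect_equal(sol2$R_eff, sol1$R_eff / 2, tolerance = 1e-9)
  # symmetric paths each carry half the current
  cm2 <- current_map(net2, sol2)
  expect_equal(cm2$values[1, 3], 0.5, tolerance = 1e-9)
  expect_equal(cm2$values[3, 3], 0.5, tolerance = 1e-9)
})

test_that("voltages match a dense full-matrix solve on random grids", {
  for (seed in 1:4) {
    nr <- sample(6:10, 1)
    r <- random_cost_grid(nr, nr, cellsize = 30, seed = seed + 200)
    src <- c(1); dst <- c(nr * nr)
    net <- build_network(r, list(src, dst))
    sol <- solve_pair(net, 1, 2)
    vd <- dense_circuit_voltages(r$values, src, dst, 30)
    # map node voltages back to cells
    got <- sol$voltages[net$node_of_cell]
    expect_equal(got, vd, tolerance = 1e-8)
    expect_equal(sol$R_eff, vd[src], tolerance = 1e-8)
  }
})

test_that("Kirchhoff conservation, reciprocity and the LCP upper bound", {
  r <- random_cost_grid(10, 10, cellsize = 30, seed = 77)
  focal <- list(cbind(c(1, 1), c(1, 2)), cbind(c(10, 10), c(9, 10)))
  net <- build_network(r, focal)
  sol <- solve_pair(net, 1, 2)
  # net current at every non-focal node ~ 0
  e <- net$edges
  flow <- numeric(net$n_nodes)
  for (k in seq_len(nrow(e))) {
    flow[e$a[k]] <- flow[e$a[k]] - sol$edge_currents[k]
    flow[e$b[k]] <- flow[e$b[k]] + sol$edge_currents[k]
  }
  expect_lt(max(abs(flow[-(1:2)])), 1e-8)
  expect_equal(flow[1], -1, tolerance = 1e-8)   # source injects 1
  expect_equal(flow[2], 1, tolerance = 1e-8)    # ground absorbs 1

  # R_eff is symmetric and bounded by the least-cost path cost
  solr <- solve_pair(net, 2, 1)
  expect_equal(sol$R_eff, solr$R_eff, tolerance = 1e-8)
  lcp <- least_cost_path(r, focal[[1]], focal[[2]])
  expect_lte(sol$R_eff, lcp$cost + 1e-9)

  # cut audit: total signed current over any column cut is 1
  v <- sol$voltages
  cutcol <- 5
  ca <- (e$cell_a - 1) %/% 10 + 1   # columns of incident cells
  cb <- (e$cell_b - 1) %/% 10 + 1
  crossing <- (ca <= cutcol & cb > cutcol) | (ca > cutcol & cb <= cutcol)
  signs <- ifelse(ca <= cutcol, 1, -1)
  expect_equal(sum((signs * sol$edge_currents)[crossing]), 1,
               tolerance = 1e-8)
})

test_that("cumulative current is additive and pair-direction invariant", {
  r <- random_cost_grid(9, 9, cellsize = 30, seed = 31)
  focal <- list(cbind(5, 1), cbind(2, 9), cbind(8, 9))
  single <- cumulative_current(r, focal[1:2], pairs = cbind(1, 2))
  net <- build_network(r, focal[1:2])
  direct <- current_map(net, solve_pair(net, 1, 2))
  expect_equal(single$current$values, direct$values, tolerance = 1e-9)

  ab <- cumulative_current(r, focal[1:2], pairs = cbind(1, 2))
  ba <- cumulative_current(r, focal[1:2], pairs = cbind(2, 1))
  expect_equal(ab$current$values, ba$current$values, tolerance = 1e-8)

  three <- cumulative_current(r, focal)
  net3 <- build_network(r, focal)
  m12 <- current_map(net3, solve_pair(net3, 1, 2))
  m13 <- current_map(net3, solve_pair(net3, 1, 3))
  expect_equal(three$current$values, m12$values + m13$values,
               tolerance = 1e-9)
})

test_that("current slicing: full mask, focal inclusion, connection sweep", {
  m <- matrix(1, 9, 21)
  r <- raster_layer(m, grid_spec(9, 21, 1))
  focal <- list(cbind(5, 2), cbind(5, 20))
  cur <- cumulative_current(r, focal)
  full <- slice_current(cur$current, 100, focal_regions = focal)
  expect_equal(sum(full$values), 9 * 21)
  expect_true(attr(full, "connected"))

  # focal cells inside the mask for any p >= 1; connection appears only
  # above some recorded threshold while the LCM mask connects at p = 1
  connected_at <- NA
  for (p in c(1, 5, 10, 15, 20, 30, 40, 60)) {
    sl <- slice_current(cur$current, p, focal_regions = focal)
    expect_equal(sl$values[5, 2], 1)
    expect_equal(sl$values[5, 20], 1)
    if (is.na(connected_at) && isTRUE(attr(sl, "connected"))) connected_at <- p
  }
  expect_false(is.na(connected_at))
  expect_gt(connected_at, 1)
})
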