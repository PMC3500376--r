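test_that("cost distance: single edges, geometry and nodata handling", {
  sp <- grid_spec(4, 4, 30)
  uni <- raster_layer(matrix(1, 4, 4), sp)
  cd <- cost_distance(uni, cbind(1, 1))
  expect_equal(cd$values[1, 2], 30)
  expect_equal(cd$values[2, 2], 30 * sqrt(2))
  expect_equal(cd$values[1, 1], 0)

  # nodata barrier forces a detour
  m <- matrix(1, 3, 3); m[, 2] <- NA; m[3, 2] <- 1
  blocked <- raster_layer(m, grid_spec(3, 3, 1))
  cdb <- cost_distance(blocked, cbind(1, 1))
  expect_true(is.na(cdb$values[1, 2]))
  expect_equal(cdb$values[3, 2], 1 + sqrt(2))  # down then diagonal around the gap
  expect_error(cost_distance(raster_layer(matrix(0, 2, 2), grid_spec(2, 2, 1)),
                             cbind(1, 1)), "positive")
})

test_that("cost distance equals the Bellman-Ford oracle on random grids", {
  for (seed in 1:6) {
    nr <- sample(8:15, 1)
    cost <- random_cost_grid(nr, nr, cellsize = 30, seed = seed)
    set.seed(seed + 100)
    src <- sample(nr * nr, 2)
    cd <- cost_distance(cost, src)
    oracle <- bf_cost_distance(cost$values, src, 30)
    expect_equal(as.numeric(cd$values), oracle, tolerance = 1e-9)
  }
})

test_that("cost distance obeys the triangle inequality", {
  cost <- random_cost_grid(12, 12, cellsize = 30, seed = 9)
  dA <- cost_distance(cost, 5)$values
  dB <- cost_distance(cost, 77)$values
  # d_A(x) <= d_A(B) + d_B(x) for all x
  expect_true(all(dA <= dA[77] + dB + 1e-9))
})

test_that("least-cost path: strips, ties, walls and degenerate calls", {
  strip <- raster_layer(matrix(1, 1, 5), grid_spec(1, 5, 30))
  p <- least_cost_path(strip, cbind(1, 1), cbind(1, 5))
  expect_equal(p$cost, 120)
  expect_equal(nrow(p$path), 5)

  same <- least_cost_path(strip, cbind(1, 3), cbind(1, 3))
  expect_equal(same$cost, 0)
  expect_equal(nrow(same$path), 1)

  # expensive wall: path routes around it; cost equals the oracle
  m <- matrix(0.1, 7, 7); m[1:6, 4] <- 50
  wall <- raster_layer(m, grid_spec(7, 7, 30))
  lp <- least_cost_path(wall, cbind(4, 1), cbind(4, 7))
  oracle <- bf_cost_distance(m, 4 + 0 * 7, 30)[4 + 6 * 7]
  expect_equal(lp$cost, oracle, tolerance = 1e-9)
  expect_true(any(lp$path[, 1] == 7))          # detours through the bottom row
  # every returned path step is an 8-neighbour move and costs add up
  steps <- diff(lp$path)
  expect_true(all(abs(steps) <= 1))
  edge_cost <- function(a, b) {
    d <- 30 * if (all(abs(a - b) == 1)) sqrt(2) else 1
    0.5 * (m[a[1], a[2]] + m[b[1], b[2]]) * d
  }
  total <- sum(vapply(seq_len(nrow(lp$path) - 1), function(i)
    edge_cost(lp$path[i, ], lp$path[i + 1, ]), numeric(1)))
  expect_equal(total, lp$cost, tolerance = 1e-9)

  disc <- matrix(1, 3, 3); disc[2, ] <- NA
  expect_error(least_cost_path(raster_layer(disc, grid_spec(3, 3, 30)),
                               cbind(1, 1), cbind(3, 3)), "unreachable")
})

test_that("corridor surface minimum equals the patch-to-patch LCP cost", {
  for (seed in 1:4) {
    cost <- random_cost_grid(15, 15, cellsize = 30, seed = seed + 50)
    src <- cbind(sample(15, 1), 1)
    dst <- cbind(sample(15, 1), 15)
    surf <- corridor_surface(cost_distance(cost, src), cost_distance(cost, dst))
    lcp <- least_cost_path(cost, src, dst)
    expect_equal(min(surf$values), lcp$cost, tolerance = 1e-9)
    # cells on the optimal path all attain the minimum
    on_path <- surf$values[lcp$path]
    expect_equal(max(abs(on_path - lcp$cost)), 0, tolerance = 1e-9)
  }
  a <- cost_distance(random_cost_grid(5, 5), 1)
  b <- cost_distance(random_cost_grid(6, 6), 1)
  expect_error(corridor_surface(a, b), "mismatch")
})

test_that("corridor slicing: percentile exactness, bases, nesting", {
  sp <- grid_spec(10, 10, 30)
  set.seed(31)
  surf <- raster_layer(matrix(sample(1:100), 10, 10), sp)
  m10 <- slice_corridor(surf, 10)
  expect_equal(sum(m10$values), 10)            # distinct values: exactly 10
  m100 <- slice_corridor(surf, 100)
  expect_equal(sum(m100$values), 100)

  vr <- slice_corridor(surf, 10, basis = "value_range")
  expect_equal(sum(vr$values), sum(surf$values <= 1 + 0.1 * 99))

  for (basis in c("area_percentile", "value_range")) {
    prev <- NULL
    for (p in c(1, 5, 10, 15, 20, 50, 100)) {
      cur <- slice_corridor(surf, p, basis)
      if (!is.null(prev)) expect_true(all(cur$values >= prev$values))
      prev <- cur
    }
  }
  expect_error(slice_corridor(raster_layer(matrix(1, 5, 5), grid_spec(5, 5, 1)), 10),
               "constant")
  expect_error(slice_corridor(surf, 0), "p > 0")
})
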