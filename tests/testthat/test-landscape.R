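test_that("covariate generation is deterministic and hits land-cover targets", {
  p <- landscape_params(nrows = 60, ncols = 60, cellsize = 1800, seed = 5)
  s1 <- gen_covariates(p, "spring")
  s2 <- gen_covariates(p, "spring")
  expect_identical(lapply(s1$layers, `[[`, "values"),
                   lapply(s2$layers, `[[`, "values"))
  expect_setequal(names(s1$layers),
                  c("dist_wells", "dist_water", "dist_roads", "ndvi",
                    "fence", "landcover", "topo_position"))
  lc <- s1$layers$landcover$values
  expect_gt(mean(lc == 3), 0.53)   # grassland ~56%
  expect_lt(mean(lc == 3), 0.59)
  expect_gt(mean(lc == 5), 0.23)   # agriculture ~26%
  expect_lt(mean(lc == 5), 0.29)
  expect_true(all(s1$layers$ndvi$values >= 0 & s1$layers$ndvi$values <= 1))
  expect_true(all(s1$layers$fence$values %in% c(0, 1)))
  expect_error(gen_covariates(landscape_params(n_wells = 0, seed = 1)),
               "empty feature set|no wells")
})

test_that("parcels and roads form the expected topology", {
  p <- landscape_params(nrows = 60, ncols = 60, cellsize = 1800,
                        parcel_rows = 2, parcel_cols = 2, n_roads = 1,
                        seed = 3)
  pr <- gen_parcels_and_roads(p)
  expect_equal(dim(pr$parcels$ownership), c(2, 2))
  # 2x2 tessellation: 6 horizontal + 6 vertical boundary segments
  expect_equal(length(pr$parcels$boundaries), 12)
  # the single road must touch two opposite extent edges
  co <- pr$roads$lines[[1]]$coords
  W <- 60 * 1800
  touches <- (min(co[, 1]) <= 0 + 1e-9 && max(co[, 1]) >= W - 1e-9) ||
             (min(co[, 2]) <= 0 + 1e-9 && max(co[, 2]) >= W - 1e-9)
  expect_true(touches)
  # different seed: same topology counts, different jitter
  pr2 <- gen_parcels_and_roads(landscape_params(nrows = 60, ncols = 60,
                                                cellsize = 1800,
                                                parcel_rows = 2,
                                                parcel_cols = 2,
                                                n_roads = 1, seed = 4))
  expect_equal(length(pr2$parcels$boundaries), 12)
  expect_false(identical(pr$parcels$corner_x, pr2$parcels$corner_x))
})

test_that("fence modelling: ownership rule, road side, dissolve", {
  sp <- grid_spec(40, 40, 30)
  # hand-built two-parcel world sharing one boundary
  mk_parcels <- function(own) {
    structure(list(
      corner_x = matrix(c(0, 0, 600, 600, 1200, 1200), 2, 3),
      corner_y = matrix(c(1200, 0, 1200, 0, 1200, 0), 2, 3),
      ownership = matrix(own, 1, 2),
      boundaries = list(
        list(coords = rbind(c(600, 0), c(600, 1200)),
             own_a = own[1], own_b = own[2]),
        list(coords = rbind(c(600, 0), c(600, 1200)),   # coincident duplicate
             own_a = own[1], own_b = own[2])),
      extent = c(1200, 1200)), class = "parcel_set")
  }
  same <- model_fences(mk_parcels(c(1, 1)), NULL, sp)
  expect_equal(n_lines(same$lines), 0)
  diff <- model_fences(mk_parcels(c(1, 2)), NULL, sp)
  expect_equal(n_lines(diff$lines), 1)    # fence present, duplicate dissolved

  road <- line_set(list(list(coords = rbind(c(0, 300), c(1200, 300)),
                             attrs = list(class = "maintained"))))
  fr <- model_fences(NULL, road, sp, rules = list(road_setback = 15))
  expect_equal(n_lines(fr$lines), 1)      # one offset line, one side only
  off <- fr$lines$lines[[1]]$coords
  expect_true(all(abs(abs(off[, 2] - 300) - 15) < 1e-9))
})

test_that("fence accuracy and ground-truth generation", {
  sp <- grid_spec(40, 40, 30)
  fences <- line_set(list(list(coords = rbind(c(0, 600), c(1200, 600)))))
  on <- data.frame(x = seq(10, 1190, length.out = 50), y = rep(600, 50))
  expect_equal(fence_accuracy(fences, on), 1.0)
  far <- data.frame(x = on$x, y = rep(700, 50))   # 100 m away
  expect_equal(fence_accuracy(fences, far, buffer_m = 15), 0.0)
  expect_error(fence_accuracy(fences, on[0, ]), "empty")

  # constructed fixture: exactly 820 of 1000 points within the buffer
  mixed <- rbind(data.frame(x = runif(820, 0, 1200), y = 600 + runif(820, -10, 10)),
                 data.frame(x = runif(180, 0, 1200), y = 600 + runif(180, 40, 90)))
  expect_equal(fence_accuracy(fences, mixed, buffer_m = 15), 0.82)

  pts <- gen_fence_truth(fences, sp, n = 500, displacement_sd = 0,
                         contamination = 0, seed = 2)
  expect_equal(nrow(pts), 500)
  expect_equal(fence_accuracy(fences, pts), 1.0)
})

test_that("truth model scores through the AHP path reproduce the surface", {
  land <- default_land()
  tm <- land$truth$spring
  expect_equal(sum(tm$variable_weights), 1)
  again <- ahp_suitability(land$stacks$spring, tm)
  expect_identical(again$values, land$true_suit$spring$values)
  expect_gt(stats::cor(valid_values(again),
                       valid_values(land$true_suit$spring),
                       method = "spearman"), 0.9)
})

test_that("line sets round-trip through GeoJSON text", {
  ls <- line_set(list(
    list(coords = rbind(c(0, 0), c(10, 5), c(20, 5)), attrs = list(id = 1)),
    list(coords = rbind(c(3, 3), c(4, 9)), attrs = list(id = 2))))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_lines_geojson(ls, f)
  back <- read_lines_geojson(f)
  expect_equal(length(back$lines), 2)
  expect_equal(back$lines[[1]]$coords, ls$lines[[1]]$coords)
})
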