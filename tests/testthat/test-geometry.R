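test_that("unit cell dimensions follow the hexagonal lattice geometry", {
  cell <- build_unit_cell(1)
  expect_equal(cell$width, sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(cell$height, 1.5, tolerance = 1e-12)

  # linear scaling
  cell2 <- build_unit_cell(2)
  expect_equal(cell2$width, sqrt(3), tolerance = 1e-12)
  expect_equal(cell2$height, 3, tolerance = 1e-12)

  # the cell holds exactly two hexagons of area (3 sqrt(3) / 8) d^2
  hex_area <- 3 * sqrt(3) / 8
  expect_equal(cell$width * cell$height, 2 * hex_area, tolerance = 1e-12)

  expect_error(build_unit_cell(-1), "positive")
  expect_error(build_unit_cell(1, vein_radius = 0.3), "radii")
})

test_that("vein and triad centers sit on lattice sites", {
  cell <- build_unit_cell(1)
  # five vein centres: four corners + cell centre
  expect_equal(nrow(cell$vein_centers), 5L)
  expect_equal(nrow(cell$triad_centers), 4L)
  # all centres inside the closed cell
  expect_true(all(cell$vein_centers[, 1] >= 0 & cell$vein_centers[, 1] <= cell$width))
  expect_true(all(cell$triad_centers[, 2] >= 0 & cell$triad_centers[, 2] <= cell$height))
  # triad centres are hexagon vertices: distance to the nearest vein centre
  # equals the circumradius d/2
  dv <- periodic_distance(cell$triad_centers, cell$vein_centers, cell)
  expect_equal(dv, rep(0.5, 4), tolerance = 1e-12)
})

test_that("periodic distance respects images and translation", {
  cell <- build_unit_cell(1)
  expect_equal(periodic_distance(cell$vein_centers[1, ],
                                 cell$vein_centers, cell), 0)
  # a point just inside the right edge is close to the left-edge target via
  # its periodic image
  p <- c(cell$width - 0.01, 0.5)
  target <- rbind(c(0, 0.5))
  d_per <- periodic_distance(p, target, cell)
  d_raw <- sqrt(sum((p - target)^2))
  expect_equal(d_per, 0.01, tolerance = 1e-12)
  expect_lt(d_per, d_raw)
  # translating by a lattice vector and reducing changes nothing
  p2 <- c(p[1] - cell$width, p[2] + cell$height)
  expect_equal(periodic_distance(p2, target, cell), d_per, tolerance = 1e-12)
  # 3x3 image tiling is already converged (brute force over 5x5)
  set.seed(42)
  pts <- cbind(runif(25) * cell$width, runif(25) * cell$height)
  img5 <- lobulemech:::periodic_images(target, cell, reach = 2L)
  d5 <- apply(pts, 1, function(q) min(sqrt((q[1] - img5[, 1])^2 +
                                           (q[2] - img5[, 2])^2)))
  expect_equal(periodic_distance(pts, target, cell), d5, tolerance = 1e-12)
  expect_error(periodic_distance(p, NULL, cell), "target")
})

test_that("distance fields vanish on their defining structures and are bounded", {
  cell <- build_unit_cell(1)
  # hexagon vertex: triad and edge distance zero
  v <- cell$triad_centers[3, , drop = FALSE]
  df_v <- distance_fields(v, cell)
  expect_equal(df_v$d_triad, 0, tolerance = 1e-12)
  expect_equal(df_v$d_edge, 0, tolerance = 1e-12)
  # lobule centre: vein and radius distance zero
  c0 <- rbind(c(cell$width / 2, cell$height / 2))
  df_c <- distance_fields(c0, cell)
  expect_equal(df_c$d_vein, 0, tolerance = 1e-12)
  expect_equal(df_c$d_radius, 0, tolerance = 1e-12)
  # geometric bound over the full raster
  g <- full_grid()
  expect_true(all(g$d_vein >= 0 & g$d_vein <= 1))
  expect_true(all(g$d_triad <= 1 & g$d_edge <= 1 & g$d_radius <= 1))
})

test_that("distance fields are periodic across cell boundaries", {
  cell <- build_unit_cell(1)
  ys <- seq(0.05, cell$height - 0.05, length.out = 7)
  left <- distance_fields(cbind(0, ys), cell)
  right <- distance_fields(cbind(cell$width, ys), cell)
  expect_equal(left, right, tolerance = 1e-12)
  xs <- seq(0.05, cell$width - 0.05, length.out = 7)
  bottom <- distance_fields(cbind(xs, 0), cell)
  top <- distance_fields(cbind(xs, cell$height), cell)
  expect_equal(bottom, top, tolerance = 1e-12)
})

test_that("normalized distance fields are scale invariant", {
  set.seed(7)
  p1 <- cbind(runif(10) * sqrt(3) / 2, runif(10) * 1.5)
  f1 <- distance_fields(p1, build_unit_cell(1))
  f2 <- distance_fields(2 * p1, build_unit_cell(2))
  expect_equal(as.data.frame(f2) / 2, as.data.frame(f1), tolerance = 1e-12)
})

test_that("region classification matches lumen geometry", {
  cell <- build_unit_cell(1, vein_radius = 0.05, triad_radius = 0.04)
  expect_equal(as.character(classify_region(cell$vein_centers[5, ], cell)),
               "VEIN_LUMEN")
  expect_equal(as.character(classify_region(cell$triad_centers[3, ], cell)),
               "TRIAD_LUMEN")
  cell0 <- build_unit_cell(1, vein_radius = 0, triad_radius = 0)
  g0 <- lobule_grid(cell0, nx = 20, ny = 40)
  expect_true(all(g0$region == "PARENCHYMA"))
  # pixel-count oracle: lumen area fraction ~ sum of circle areas
  g <- full_grid()
  frac_pix <- mean(g$region != "PARENCHYMA")
  frac_geo <- (2 * pi * 0.05^2 + 4 * pi * 0.04^2) /
    (cell$width * cell$height)
  expect_equal(frac_pix, frac_geo, tolerance = 0.15)
})
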