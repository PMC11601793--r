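test_that("radial coordinate is bounded, oriented and smooth", {
  g <- full_grid()
  xi <- radial_coordinate(g)
  expect_true(all(xi >= 0 & xi <= 1))
  # near the hexagon boundary xi ~ 0; at the lobule centre xi ~ 1
  expect_lt(xi[which.min(g$d_edge)], 0.05)
  expect_gt(xi[which.min(g$d_vein)], 0.95)
  # continuity between horizontal neighbours at 80x160 resolution
  ximat <- matrix(xi, nrow = 80)
  expect_lt(max(abs(diff(ximat))), 0.1)
  expect_lt(max(abs(t(diff(t(ximat))))), 0.1)
})

test_that("fat profile hits its endpoints and interpolates in sqrt(xi)", {
  expect_equal(fat_profile(0, 0.4, 0.1), 0.1)
  expect_equal(fat_profile(1, 0.4, 0.1), 0.4)
  expect_equal(fat_profile(c(0, 0.5, 1), 0.3, 0.3), rep(0.3, 3))
  expect_equal(fat_profile(0.25, 0.4, 0), sqrt(0.25) * 0.4)
  expect_equal(fat_profile(0.25, 0.4, 0, profile = "linear"), 0.1)
})

test_that("endpoint calibration reproduces the target mean exactly", {
  g <- full_grid()
  expect_equal(calibrate_endpoints(0, 1, g), c(Vin = 0, Vout = 0))
  mask <- g$region == "PARENCHYMA"
  xi <- radial_coordinate(g)
  for (pattern in 1:2) {
    for (target in c(0.05, 0.2, 0.4)) {
      e <- calibrate_endpoints(target, pattern, g)
      V <- fat_profile(xi, e["Vin"], e["Vout"])
      expect_equal(mean(V[mask]), target, tolerance = 1e-10)
      expect_true(all(e >= 0 & e <= 0.5 + 1e-12))
    }
  }
  # monotonicity of the solved centre fraction in the target (Pattern 1)
  vins <- vapply(seq(0.02, 0.2, by = 0.02),
                 function(t) calibrate_endpoints(t, 1, g)[["Vin"]],
                 numeric(1))
  expect_true(all(diff(vins) > 0))
  # high targets clamp the peak endpoint at the 50% cap
  e_hi <- calibrate_endpoints(0.4, 1, g)
  expect_equal(e_hi[["Vin"]], 0.5)
  expect_gt(e_hi[["Vout"]], 0)
})

test_that("fat fields are reproducible, capped and pattern-consistent", {
  g <- full_grid()
  f1 <- generate_fat_field(0.2, pattern = 1, seed = 11, grid = g)
  f2 <- generate_fat_field(0.2, pattern = 1, seed = 11, grid = g)
  expect_identical(f1$fat, f2$fat)
  f3 <- generate_fat_field(0.2, pattern = 1, seed = 12, grid = g)
  expect_false(identical(f1$fat, f3$fat))

  # no pixel exceeds the cap after noise; lumens carry no fat
  expect_true(all(f1$fat >= 0 & f1$fat <= 0.5))
  expect_true(all(f1$fat[f1$region != "PARENCHYMA"] == 0))

  # zero noise recovers the calibrated profile
  f0 <- generate_fat_field(0.2, pattern = 1, seed = 11, grid = g,
                           noise_sigma = 0)
  xi <- radial_coordinate(g)
  V <- fat_profile(xi, attr(f0, "Vin"), attr(f0, "Vout"))
  V[g$region != "PARENCHYMA"] <- 0
  expect_equal(f0$fat, V, tolerance = 1e-12)

  # pattern contrast: pericentral fat peaks at the centre, boundary fat at
  # the rim
  p1 <- generate_fat_field(0.2, pattern = 1, seed = 5, grid = g)
  p2 <- generate_fat_field(0.2, pattern = 2, seed = 5, grid = g)
  core <- xi > 0.8 & g$region == "PARENCHYMA"
  rim <- xi < 0.2 & g$region == "PARENCHYMA"
  expect_gt(mean(p1$fat[core]), mean(p1$fat[rim]))
  expect_lt(mean(p2$fat[core]), mean(p2$fat[rim]))
})

test_that("clipping bias keeps the realized mean within one percent", {
  g <- full_grid()
  realized <- vapply(1:20, function(s) {
    attr(generate_fat_field(0.2, pattern = 1, seed = s, grid = g),
         "realized_mean")
  }, numeric(1))
  expect_true(all(abs(realized - 0.2) < 0.01))
})

test_that("fat-to-modulus mapping matches the scalar conversion pixelwise", {
  g <- full_grid()
  f <- generate_fat_field(0.16, pattern = 1, seed = 3, grid = g)
  G <- fat_to_modulus_field(f, kv_matrix(), 100)
  Gm <- complex_modulus(kv_matrix(), 100)
  Gf <- complex(real = 0, imaginary = 2 * pi * 100 * 0.4)
  set.seed(1)
  idx <- sample(which(f$region == "PARENCHYMA"), 10)
  expect_equal(G[idx], effective_fat_modulus(f$fat[idx], Gm, Gf),
               tolerance = 1e-12)
  # lumens get the soft modulus
  lum <- which(f$region != "PARENCHYMA")[1]
  expect_equal(G[lum], 1e-3 * Gm)

  # zero fat: uniform matrix modulus on parenchyma
  f0 <- generate_fat_field(0, pattern = 1, seed = 3, grid = g)
  G0 <- fat_to_modulus_field(f0, kv_matrix(), 100)
  expect_true(all(G0[f0$region == "PARENCHYMA"] == Gm))

  # storage varies much more (relatively) than loss across the raster
  par <- f$region == "PARENCHYMA"
  rel_range <- function(x) diff(range(x)) / stats::median(x)
  expect_gt(rel_range(Re(G[par])), 3 * rel_range(Im(G[par])))
})
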