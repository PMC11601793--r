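test_that("homogenization of a lumen-free healthy cell is the matrix modulus", {
  cell0 <- build_unit_cell(1, vein_radius = 0, triad_radius = 0)
  g0 <- lobule_grid(cell0)
  micro <- build_microstructure(seed = 1, grid = g0, cell = cell0)
  res <- homogenize(micro, nx = 8, ny = 16)
  expect_equal(res$G_eff, G_HEALTHY_100, tolerance = 1e-9)
  expect_equal(res$tau, 0.8 / 2000, tolerance = 1e-9)
})

test_that("effective tensor is major-symmetric and scale invariant", {
  cell <- default_cell()
  g <- lobule_grid(cell)
  micro <- build_microstructure(fat_target = 0.2, seed = 2, grid = g,
                                noise_sigma = 0)
  res <- homogenize(micro, nx = 8, ny = 16, full_tensor = TRUE)
  EH <- res$E_H
  expect_equal(dim(EH), c(3L, 3L))
  expect_lt(max(Mod(EH - t(EH))) / max(Mod(EH)), 1e-8)

  # doubling every length leaves the effective modulus unchanged
  cell2 <- build_unit_cell(2, vein_radius = 0.1, triad_radius = 0.08)
  g2 <- lobule_grid(cell2)
  micro2 <- build_microstructure(fat_target = 0.2, seed = 2, grid = g2,
                                 cell = cell2, noise_sigma = 0)
  res2 <- homogenize(micro2, nx = 8, ny = 16, mesh = build_mesh(8, 16, cell2))
  res1 <- homogenize(micro, nx = 8, ny = 16)
  expect_lt(Mod(res1$G_eff - res2$G_eff) / Mod(res1$G_eff), 1e-6)
})

test_that("average-stress extraction matches an independent integrand average", {
  # second route: recompute < E (e0 + eps(v)) > with an explicit per-element
  # loop over the returned fluctuation field
  cell <- default_cell()
  g <- lobule_grid(cell)
  micro <- build_microstructure(fat_target = 0.15, cpa_target = 0.05,
                                seed = 3, grid = g)
  mesh <- small_mesh(8, 16)
  Gpix <- modulus_raster(micro)
  sol <- solve_cell(Gpix, mesh, keep_fields = TRUE)
  u <- sol$u$mode3
  Gg <- material_at_gauss(Gpix, mesh)
  tpl <- lobulemech:::element_templates(mesh, 0.4999)
  e0 <- c(0, 0, 1)
  acc <- complex(real = rep(0, 3))
  for (e in seq_len(mesh$nelem)) {
    ue <- u[mesh$edof[e, ]]
    for (gp in 1:4) {
      eps <- as.vector(mesh$Bmats[[gp]] %*% ue) + e0
      acc <- acc + mesh$detJ * Gg[e, gp] * as.vector(tpl$EA %*% eps)
    }
    lam <- tpl$b * mean(Gg[e, ])
    eps0 <- as.vector(tpl$B0 %*% ue) + e0
    acc <- acc + tpl$w0 * lam * as.vector(tpl$EB %*% eps0)
  }
  acc <- acc / mesh$area
  expect_lt(Mod(acc[3] - sol$G_eff) / Mod(sol$G_eff), 1e-10)
})

test_that("phase interchange: matrix-modulus collagen leaves the cell unchanged", {
  g <- full_grid()
  micro <- build_microstructure(cpa_target = 0.08, seed = 5, grid = g)
  base <- build_microstructure(cpa_target = 0, seed = 5, grid = g)
  mesh <- small_mesh(8, 16)
  # purely elastic matrix so collagen at the same modulus is invisible
  em <- material_elastic(2000)
  r_fib <- homogenize(micro, matrix_model = em, collagen_modulus = 2000,
                      mesh = mesh)
  r_base <- homogenize(base, matrix_model = em, mesh = mesh)
  expect_lt(Mod(r_fib$G_eff - r_base$G_eff) / Mod(r_base$G_eff), 1e-9)
})

test_that("ensembles are seeded, reproducible and summarised correctly", {
  g <- full_grid()
  ens <- run_ensemble(3, base_seed = 7, fat_target = 0.1, nx = 8, ny = 16,
                      grid = g)
  expect_s3_class(ens, "homog_ensemble")
  expect_equal(nrow(ens), 3L)
  expect_equal(ens$seed, 7:9)
  # n = 1 reproduces a single run
  one <- run_ensemble(1, base_seed = 8, fat_target = 0.1, nx = 8, ny = 16,
                      grid = g)
  expect_equal(one$storage, ens$storage[2], tolerance = 1e-12)
  # deterministic microstructure (no fat, no collagen): zero spread
  flat <- run_ensemble(2, base_seed = 1, nx = 8, ny = 16, grid = g)
  expect_equal(stats::sd(flat$storage), 0)
  gl <- glance(ens)
  expect_equal(gl$n, 3L)
  expect_equal(gl$storage_mean, mean(ens$storage))
  td <- tidy(homogenize(build_microstructure(seed = 1, grid = g),
                        mesh = small_mesh(8, 16)))
  expect_equal(nrow(td), 1L)
})

test_that("Voigt-Reuss bounds hold for random elastic two-phase cells", {
  mesh <- small_mesh(8, 16)
  set.seed(99)
  for (k in 1:20) {
    frac <- stats::runif(1, 0.05, 0.4)
    mask <- stats::runif(80 * 160) < frac
    G1 <- 2000
    G2 <- stats::runif(1, 10000, 80000)
    Gpix <- ifelse(mask, G2, G1) + 0i
    sol <- solve_cell(Gpix, mesh)
    # realized fractions as the FE sees them (Gauss sampling)
    Gg <- material_at_gauss(Gpix, mesh)
    f2 <- mean(Re(Gg) == G2)
    rep_ <- bounds_check(Re(sol$G_eff), c(G1, G2), c(1 - f2, f2))
    expect_true(rep_$within)
  }
  # degenerate homogeneous case: both bounds collapse onto the modulus
  hom <- bounds_check(2000, c(2000, 2000), c(0.5, 0.5))
  expect_equal(hom$reuss, 2000)
  expect_equal(hom$voigt, 2000)
  # printed two-phase example: 10% of 60 kPa in 2 kPa
  b <- bounds_check(3000, c(2000, 60000), c(0.9, 0.1))
  expect_equal(b$reuss, 2214, tolerance = 1e-3)
  expect_equal(b$voigt, 7800)
  expect_error(bounds_check(1, c(1, 2), c(0.5, 0.4)), "sum")
})
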