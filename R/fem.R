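# Frequency-domain viscoelastic finite elements on the periodic unit cell.
#
# Plane strain, 8-node serendipity quadrilaterals (QUAD8) on a structured
# rectangular mesh, 2x2 Gauss quadrature (reduced for QUAD8, which both
# follows the discretization the framework is calibrated on and avoids
# volumetric locking at Poisson ratios near 1/2). The complex-valued
# constitutive law G*(x) E0(nu) enters either as a complex operator solved by
# a storage-part Cholesky with a fixed-point loss coupling, or as the
# equivalent real 2x2 block system.

# QUAD8 local node coordinates, corner 1..4 CCW then midsides 5..8
quad8_local <- cbind(
  xi = c(-1, 1, 1, -1, 0, 1, 0, -1),
  eta = c(-1, -1, 1, 1, -1, 0, 1, 0)
)

# shape-function derivative matrix (8 x 2: dN/dxi, dN/deta) at (xi, eta)
quad8_dN <- function(xi, eta) {
  dN <- matrix(0, 8, 2)
  for (a in 1:4) {
    xa <- quad8_local[a, 1]; ya <- quad8_local[a, 2]
    dN[a, 1] <- 0.25 * xa * (1 + eta * ya) * (2 * xi * xa + eta * ya)
    dN[a, 2] <- 0.25 * ya * (1 + xi * xa) * (xi * xa + 2 * eta * ya)
  }
  for (a in c(5, 7)) {
    ya <- quad8_local[a, 2]
    dN[a, 1] <- -xi * (1 + eta * ya)
    dN[a, 2] <- 0.5 * (1 - xi^2) * ya
  }
  for (a in c(6, 8)) {
    xa <- quad8_local[a, 1]
    dN[a, 1] <- 0.5 * xa * (1 - eta^2)
    dN[a, 2] <- -eta * (1 + xi * xa)
  }
  dN
}

# plane-strain constitutive matrix per unit shear modulus, Voigt
# [e11, e22, gamma12]
plane_strain_E0 <- function(nu) {
  b <- 2 * nu / (1 - 2 * nu)
  matrix(c(b + 2, b, 0,
           b, b + 2, 0,
           0, 0, 1), 3, 3)
}

#' Build a structured periodic QUAD8 mesh of the unit cell
#'
#' Uniform `nx` x `ny` mesh of 8-node serendipity quadrilaterals spanning
#' the cell, with 2x2 Gauss quadrature data and the periodic master/slave
#' node pairing (right to left, top to bottom, four corners to one master)
#' precomputed. At the default 40 x 80 each element covers a 2 x 2 block of
#' the 80 x 160 material raster and each Gauss point falls nearest a
#' distinct pixel.
#'
#' @param nx,ny Element counts across width and height (default 40 x 80).
#' @param cell A [build_unit_cell()] object.
#' @return An object of class `fe_mesh`.
#' @export
build_mesh <- function(nx = 40, ny = 80, cell = build_unit_cell()) {
  if (nx < 2 || ny < 2) stop("`nx`, `ny` must be >= 2.", call. = FALSE)
  hx <- cell$width / nx
  hy <- cell$height / ny
  gw <- 2 * nx + 1
  gh <- 2 * ny + 1
  # node ids on the (2nx+1) x (2ny+1) lattice; odd-odd positions are not
  # serendipity nodes
  keep <- outer(0:(gw - 1), 0:(gh - 1),
                function(i, j) !(i %% 2 == 1 & j %% 2 == 1))
  idx <- matrix(NA_integer_, gw, gh)
  idx[keep] <- seq_len(sum(keep))
  nnode <- sum(keep)
  gi <- (row(idx) - 1)[keep]
  gj <- (col(idx) - 1)[keep]
  nodes <- cbind(x = gi * hx / 2, y = gj * hy / 2)

  el <- expand.grid(ei = 0:(nx - 1), ej = 0:(ny - 1))
  at <- function(i, j) idx[cbind(i + 1, j + 1)]
  conn <- cbind(
    at(2 * el$ei, 2 * el$ej), at(2 * el$ei + 2, 2 * el$ej),
    at(2 * el$ei + 2, 2 * el$ej + 2), at(2 * el$ei, 2 * el$ej + 2),
    at(2 * el$ei + 1, 2 * el$ej), at(2 * el$ei + 2, 2 * el$ej + 1),
    at(2 * el$ei + 1, 2 * el$ej + 2), at(2 * el$ei, 2 * el$ej + 1)
  )

  # periodic master map on the lattice: wrap i = 2nx -> 0, j = 2ny -> 0
  mi <- ifelse(gi == 2 * nx, 0L, gi)
  mj <- ifelse(gj == 2 * ny, 0L, gj)
  master_node <- idx[cbind(mi + 1, mj + 1)]
  pinned <- idx[1, 1]  # corner master, pinned in both components

  # reduced dof numbering over master nodes, excluding the pinned node
  is_master <- master_node == seq_len(nnode)
  red_id <- integer(nnode)
  keep_master <- is_master & seq_len(nnode) != pinned
  red_id[keep_master] <- seq_len(sum(keep_master))

  ndof <- 2L * nnode
  nred <- 2L * sum(keep_master)
  full_dof <- seq_len(ndof)
  node_of_dof <- (full_dof + 1L) %/% 2L
  comp <- 2L - full_dof %% 2L  # 1 = x, 2 = y... (odd dof = x)
  mnode <- master_node[node_of_dof]
  keep_dof <- mnode != pinned
  Tred <- Matrix::sparseMatrix(
    i = full_dof[keep_dof],
    j = 2L * red_id[mnode[keep_dof]] - (2L - comp[keep_dof]) - 0L,
    x = 1,
    dims = c(ndof, nred)
  )

  # 2x2 Gauss data on the (constant-Jacobian) reference element
  g1 <- 1 / sqrt(3)
  gpts <- cbind(xi = c(-g1, g1, g1, -g1), eta = c(-g1, -g1, g1, g1))
  detJ <- hx * hy / 4
  Bmats <- lapply(1:4, function(g) {
    dN <- quad8_dN(gpts[g, 1], gpts[g, 2])
    dNdx <- dN[, 1] * 2 / hx
    dNdy <- dN[, 2] * 2 / hy
    B <- matrix(0, 3, 16)
    B[1, seq(1, 16, 2)] <- dNdx
    B[2, seq(2, 16, 2)] <- dNdy
    B[3, seq(1, 16, 2)] <- dNdy
    B[3, seq(2, 16, 2)] <- dNdx
    B
  })

  # element dof index table (nelem x 16), full and reduced numbering
  # (reduced: master-node dofs, pinned node = 0)
  edof <- matrix(0L, nrow(conn), 16)
  edof[, seq(1, 16, 2)] <- 2L * conn - 1L
  edof[, seq(2, 16, 2)] <- 2L * conn
  node_red <- ifelse(keep_master, red_id, red_id[master_node])
  node_red[master_node == pinned] <- 0L
  edof_red <- matrix(0L, nrow(conn), 16)
  cr <- matrix(node_red[conn], nrow(conn), 8)
  edof_red[, seq(1, 16, 2)] <- ifelse(cr > 0L, 2L * cr - 1L, 0L)
  edof_red[, seq(2, 16, 2)] <- ifelse(cr > 0L, 2L * cr, 0L)

  structure(
    list(nx = nx, ny = ny, hx = hx, hy = hy, cell = cell,
         nodes = nodes, conn = conn, nnode = nnode, ndof = ndof,
         nred = nred, nelem = nrow(conn), edof = edof,
         edof_red = edof_red, Bmats = Bmats, gpts = gpts,
         detJ = detJ, area = cell$width * cell$height,
         master_node = master_node, pinned = pinned, T = Tred,
         cache = new.env(parent = emptyenv())),
    class = "fe_mesh"
  )
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d x %d QUAD8, %d nodes, %d reduced dofs\n",
              x$nx, x$ny, x$nnode, ncol(x$T)))
  invisible(x)
}

#' Sample a pixel raster at the Gauss points
#'
#' Nearest-grid-point lookup of a per-pixel value field (pixel order as in
#' [lobule_grid()]: `i` fastest) at the 2x2 Gauss points of every element.
#'
#' @param values Vector of per-pixel values (length `ngx * ngy`), numeric or
#'   complex.
#' @param mesh An `fe_mesh`.
#' @param ngx,ngy Raster dimensions.
#' @return Matrix (`nelem` x 4) of values at the Gauss points.
#' @export
material_at_gauss <- function(values, mesh, ngx = 80, ngy = 160) {
  stopifnot(length(values) == ngx * ngy)
  el <- expand.grid(ei = 0:(mesh$nx - 1), ej = 0:(mesh$ny - 1))
  dxg <- mesh$cell$width / ngx
  dyg <- mesh$cell$height / ngy
  out <- matrix(values[1] * 0, mesh$nelem, 4)
  for (g in 1:4) {
    x <- (el$ei + 0.5 + mesh$gpts[g, 1] / 2) * mesh$hx
    y <- (el$ej + 0.5 + mesh$gpts[g, 2] / 2) * mesh$hy
    px <- pmin(pmax(floor(x / dxg) + 1, 1), ngx)
    py <- pmin(pmax(floor(y / dyg) + 1, 1), ngy)
    out[, g] <- values[(py - 1L) * ngx + px]
  }
  out
}

# Element stiffness/load generators. Near-incompressibility is handled by
# selective reduced integration: the shear part E_A = G * diag-dominant
# template is integrated at the 2x2 points, the volumetric part
# E_B = lambda * (volumetric outer product) at the element centroid only,
# with lambda taken as b * mean(G) over the element's Gauss points
# (b = 2 nu / (1 - 2 nu)). With a uniform Poisson ratio every template is
# shared by all (congruent) elements, so assembly reduces to two small
# matrix products.
element_shear_E <- function() {
  matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 1), 3, 3)
}
element_vol_E <- function() {
  matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3)
}

element_templates <- function(mesh, nu) {
  EA <- element_shear_E()
  EB <- element_vol_E()
  b <- 2 * nu / (1 - 2 * nu)
  KA <- matrix(0, 4, 256)
  FA <- vector("list", 3)
  for (m in 1:3) FA[[m]] <- matrix(0, 4, 16)
  for (g in 1:4) {
    B <- mesh$Bmats[[g]]
    KA[g, ] <- as.vector(mesh$detJ * crossprod(B, EA %*% B))
    for (m in 1:3) {
      e0 <- numeric(3); e0[m] <- 1
      FA[[m]][g, ] <- mesh$detJ * as.vector(crossprod(B, EA %*% e0))
    }
  }
  # centroid (xi = eta = 0) strain-displacement matrix, 1-point rule
  dN <- quad8_dN(0, 0)
  B0 <- matrix(0, 3, 16)
  B0[1, seq(1, 16, 2)] <- dN[, 1] * 2 / mesh$hx
  B0[2, seq(2, 16, 2)] <- dN[, 2] * 2 / mesh$hy
  B0[3, seq(1, 16, 2)] <- dN[, 2] * 2 / mesh$hy
  B0[3, seq(2, 16, 2)] <- dN[, 1] * 2 / mesh$hx
  w0 <- 4 * mesh$detJ
  KB <- matrix(as.vector(w0 * crossprod(B0, EB %*% B0)), 1, 256)
  FB <- lapply(1:3, function(m) {
    e0 <- numeric(3); e0[m] <- 1
    matrix(w0 * as.vector(crossprod(B0, EB %*% e0)), 1, 16)
  })
  list(EA = EA, EB = EB, b = b, KA = KA, KB = KB, FA = FA, FB = FB,
       B0 = B0, w0 = w0)
}

# Lazily built per-mesh assembly structure: reduced-dof triplet indices,
# their positions in the fixed CSC sparsity pattern, and the pattern matrix
# itself. The pattern (and later the symbolic Cholesky) is shared by every
# realization on the same mesh.
assembly_plan <- function(mesh) {
  cache <- mesh$cache
  if (!is.null(cache$plan)) return(cache$plan)
  rr <- rep(1:16, times = 16)
  cc <- rep(1:16, each = 16)
  II <- as.vector(mesh$edof_red[, rr])
  JJ <- as.vector(mesh$edof_red[, cc])
  keep <- II > 0L & JJ > 0L
  II <- II[keep]; JJ <- JJ[keep]
  n <- mesh$nred
  P <- Matrix::sparseMatrix(i = II, j = JJ, x = 0, dims = c(n, n))
  col_of <- rep.int(seq_len(n), diff(P@p))
  key_csc <- (col_of - 1) * n + (P@i + 1)
  pos <- match((JJ - 1) * n + II, key_csc)
  # triplet -> CSC accumulation as a sparse matvec (much faster than rowsum)
  Aacc <- Matrix::sparseMatrix(i = pos, j = seq_along(pos), x = 1,
                               dims = c(length(P@x), length(pos)))
  fidx <- as.vector(mesh$edof_red)
  fkeep <- fidx > 0L
  Facc <- Matrix::sparseMatrix(i = fidx[fkeep], j = seq_len(sum(fkeep)),
                               x = 1, dims = c(n, sum(fkeep)))
  plan <- list(keep = keep, P = P, Aacc = Aacc, Facc = Facc, fkeep = fkeep)
  cache$plan <- plan
  plan
}

# scatter triplet values into a fresh matrix with the cached CSC pattern
fill_pattern <- function(plan, vals) {
  Matrix::sparseMatrix(i = plan$P@i, p = plan$P@p,
                       x = as.vector(plan$Aacc %*% vals),
                       dims = plan$P@Dim, index1 = FALSE, check = FALSE)
}

# Assemble the reduced complex operator (real and imaginary sparse parts)
# and the reduced eigenstrain load for each requested strain mode.
# G_gauss: nelem x 4 complex matrix of shear moduli at Gauss points.
assemble_reduced <- function(G_gauss, mesh, nu = 0.4999, modes = 3L) {
  tpl <- element_templates(mesh, nu)
  plan <- assembly_plan(mesh)
  lam <- tpl$b * rowMeans(G_gauss)  # element volumetric modulus (complex)
  Gr <- Re(G_gauss)
  Gi <- Im(G_gauss)
  has_loss <- any(Gi != 0)
  kvals <- function(Gpart, lpart) {
    as.vector(Gpart %*% tpl$KA + lpart %*% tpl$KB)[plan$keep]
  }
  Kr_red <- fill_pattern(plan, kvals(Gr, matrix(Re(lam), ncol = 1)))
  Ki_red <- if (has_loss) {
    fill_pattern(plan, kvals(Gi, matrix(Im(lam), ncol = 1)))
  } else NULL
  fvals <- function(Gpart, lpart, m) {
    v <- as.vector(Gpart %*% tpl$FA[[m]] + lpart %*% tpl$FB[[m]])[plan$fkeep]
    as.vector(plan$Facc %*% v)
  }
  loads <- lapply(modes, function(m) {
    fr <- fvals(Gr, matrix(Re(lam), ncol = 1), m)
    fi <- if (has_loss) fvals(Gi, matrix(Im(lam), ncol = 1), m) else 0
    complex(real = fr, imaginary = fi)
  })
  names(loads) <- paste0("mode", modes)
  list(Kr = Kr_red, Ki = Ki_red, loads = loads, tpl = tpl, modes = modes,
       cache = mesh$cache)
}

# Solve the reduced complex system K u = b for one or more right-hand
# sides. Default: Cholesky of the (SPD) storage operator plus fixed-point
# iteration on the loss coupling; falls back to (or can be forced to) a
# sparse LU of the equivalent real 2x2 block system.
solve_reduced <- function(op, b, method = c("fixed_point", "block_lu"),
                          tol = 1e-10, maxit = 200L) {
  method <- match.arg(method)
  Kr <- op$Kr
  Ki <- op$Ki
  if (method == "block_lu") {
    n <- nrow(Kr)
    if (is.null(Ki)) Ki <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                                x = numeric(), dims = c(n, n))
    Kb <- rbind(cbind(Kr, -Ki), cbind(Ki, Kr))
    ub <- as.vector(Matrix::solve(Kb, c(Re(b), Im(b))))
    return(complex(real = ub[seq_len(n)], imaginary = ub[n + seq_len(n)]))
  }
  # supernodal Cholesky of the (SPD) storage operator
  Ks <- Matrix::forceSymmetric(Kr)
  ch <- Matrix::Cholesky(Ks, LDL = FALSE, super = TRUE)
  if (is.null(Ki)) {
    ur <- as.vector(Matrix::solve(ch, Re(b)))
    ui <- as.vector(Matrix::solve(ch, Im(b)))
    return(complex(real = ur, imaginary = ui))
  }
  br <- Re(b); bi <- Im(b)
  bnorm <- sqrt(sum(br^2) + sum(bi^2))
  if (bnorm == 0) return(complex(real = numeric(nrow(Kr))))
  ur <- as.vector(Matrix::solve(ch, br))
  ui <- as.vector(Matrix::solve(ch, bi))
  res_prev <- Inf
  for (it in seq_len(maxit)) {
    ur <- as.vector(Matrix::solve(ch, br + Ki %*% ui))
    ui <- as.vector(Matrix::solve(ch, bi - Ki %*% ur))
    rr <- as.vector(Kr %*% ur - Ki %*% ui) - br
    ri <- as.vector(Ki %*% ur + Kr %*% ui) - bi
    res <- sqrt(sum(rr^2) + sum(ri^2)) / bnorm
    if (res < tol) return(complex(real = ur, imaginary = ui))
    if (res > 0.9 * res_prev) break  # stagnated (round-off floor) or diverging
    res_prev <- res
  }
  if (res < 1e-8) return(complex(real = ur, imaginary = ui))
  # loss coupling too strong for the fixed point; use the exact block solve
  solve_reduced(op, b, method = "block_lu")
}

# Volume-averaged complex stress (Voigt 3-vector) for fluctuation u_full
# under unit macroscopic strain mode e0 (Voigt index m), consistent with
# the selectively reduced-integrated operator: shear stress from the 2x2
# points, volumetric stress from the centroid strain.
average_stress <- function(u_full, G_gauss, mesh, tpl, mode) {
  e0 <- numeric(3); e0[mode] <- 1
  sig <- complex(real = rep(0, 3))
  Ue <- matrix(u_full[mesh$edof], mesh$nelem, 16)
  wJ <- mesh$detJ
  for (g in 1:4) {
    eps <- Ue %*% t(mesh$Bmats[[g]])
    eps <- sweep(eps, 2, e0, "+")
    sg <- (eps %*% tpl$EA) * G_gauss[, g]
    sig <- sig + wJ * colSums(sg)
  }
  lam <- tpl$b * rowMeans(G_gauss)
  eps0 <- sweep(Ue %*% t(tpl$B0), 2, e0, "+")
  sig <- sig + tpl$w0 * colSums((eps0 %*% tpl$EB) * lam)
  sig / mesh$area
}

#' Solve the periodic cell problem for a macroscopic strain mode
#'
#' Assembles the complex viscoelastic operator for a per-pixel modulus
#' raster, applies the eigenstrain load of a unit macroscopic strain
#' (engineering shear \eqn{\gamma_{12} = 1} for the default mode 3), solves
#' for the periodic fluctuation field and returns the volume-averaged
#' complex stress. `<sigma_12>` under unit shear is the homogenized complex
#' shear modulus.
#'
#' @param G_pixel Complex per-pixel shear modulus raster (length
#'   `ngx * ngy`, pixel order as in [lobule_grid()]).
#' @param mesh An [build_mesh()] object.
#' @param ngx,ngy Raster dimensions (default 80 x 160).
#' @param nu Poisson ratio (near 1/2 for near-incompressibility).
#' @param modes Voigt strain modes to solve (1 = e11, 2 = e22, 3 =
#'   gamma12); default shear only.
#' @param method Linear solver, see Details in the package vignette.
#' @param keep_fields If `TRUE`, returns the nodal fluctuation fields.
#' @return A list with `sigma_avg` (list of Voigt complex 3-vectors per
#'   mode), `G_eff` (complex, `<sigma_12>` of the shear mode if solved),
#'   and optionally `u` (complex `ndof` vectors per mode).
#' @export
solve_cell <- function(G_pixel, mesh, ngx = 80, ngy = 160, nu = 0.4999,
                       modes = 3L, method = c("fixed_point", "block_lu"),
                       keep_fields = FALSE) {
  method <- match.arg(method)
  G_gauss <- material_at_gauss(G_pixel, mesh, ngx, ngy)
  op <- assemble_reduced(G_gauss, mesh, nu, modes = modes)
  out_sigma <- list()
  out_u <- list()
  for (k in seq_along(modes)) {
    m <- modes[k]
    u_red <- solve_reduced(op, -op$loads[[k]], method = method)
    u_full <- as.vector(mesh$T %*% Re(u_red)) +
      1i * as.vector(mesh$T %*% Im(u_red))
    out_sigma[[paste0("mode", m)]] <-
      average_stress(u_full, G_gauss, mesh, op$tpl, m)
    if (keep_fields) out_u[[paste0("mode", m)]] <- u_full
  }
  G_eff <- if (3L %in% modes) out_sigma[["mode3"]][3] else NULL
  list(sigma_avg = out_sigma, G_eff = G_eff,
       u = if (keep_fields) out_u else NULL)
}
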