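#' Homogenized complex shear modulus of a microstructure
#'
#' Runs the periodic-cell finite-element solve for a synthetic
#' microstructure and extracts the effective (homogenized) complex shear
#' modulus \eqn{G^*_{\mathrm{eff}} = \langle\sigma_{12}\rangle} under unit
#' macroscopic engineering shear, together with the effective relaxation
#' time \eqn{\tau = G''/(\omega G')}. With `full_tensor = TRUE` all three
#' plane-strain Voigt modes are solved and the effective modulus tensor
#' \eqn{E^H} (volume average of the stress over the cell per unit applied
#' strain, fluctuation included) is returned.
#'
#' @param micro A `microstructure` tibble (from [build_microstructure()]),
#'   or any lobule grid with `fat` and optionally `collagen` columns.
#' @param frequency Frequency, Hz (default 100).
#' @param matrix_model [material_model] of the healthy tissue matrix.
#' @param collagen_modulus Elastic collagen shear modulus, Pa.
#' @param fat_viscosity Fat viscosity, Pa s.
#' @param lumen_factor Lumen modulus fraction of the matrix modulus.
#' @param mesh An [build_mesh()] object; built as `nx` x `ny` on the grid's
#'   cell when omitted.
#' @param nx,ny Mesh size when `mesh` is omitted (default 40 x 80).
#' @param nu Poisson ratio (default 0.4999, near-incompressible).
#' @param full_tensor Solve all three strain modes and return `E_H`.
#' @param method Linear solver passed to [solve_cell()].
#' @return An object of class `homog_result`: list with `G_eff` (complex,
#'   Pa), `storage`, `loss`, `tau`, `frequency`, `E_H` (complex 3x3 or
#'   `NULL`), `meta` (realized fractions, mesh, materials, seed).
#' @export
homogenize <- function(micro, frequency = 100,
                       matrix_model = material_kelvin_voigt(2000, 0.8),
                       collagen_modulus = 60e3, fat_viscosity = 0.4,
                       lumen_factor = 1e-3, mesh = NULL, nx = 40, ny = 80,
                       nu = 0.4999, full_tensor = FALSE,
                       method = c("fixed_point", "block_lu")) {
  method <- match.arg(method)
  ngx <- attr(micro, "nx") %||% 80
  ngy <- attr(micro, "ny") %||% 160
  cell <- attr(micro, "cell") %||% build_unit_cell()
  if (is.null(mesh)) mesh <- build_mesh(nx, ny, cell)
  G_pixel <- modulus_raster(micro, matrix_model, frequency,
                            collagen_modulus, fat_viscosity, lumen_factor)
  modes <- if (full_tensor) 1:3 else 3L
  sol <- solve_cell(G_pixel, mesh, ngx, ngy, nu, modes = modes,
                    method = method)
  G_eff <- sol$G_eff
  E_H <- NULL
  if (full_tensor) {
    E_H <- do.call(cbind, sol$sigma_avg)
    dimnames(E_H) <- NULL
  }
  structure(
    list(G_eff = G_eff, storage = Re(G_eff), loss = Im(G_eff),
         tau = relaxation_time(G_eff, frequency),
         frequency = frequency, E_H = E_H,
         meta = list(
           seed = attr(micro, "seed"),
           fat_target = attr(micro, "fat_target") %||% NA_real_,
           realized_fat = attr(micro, "realized_fat") %||% NA_real_,
           cpa_target = attr(micro, "cpa_target") %||% NA_real_,
           realized_cpa = attr(micro, "realized_cpa") %||% NA_real_,
           fat_pattern = attr(micro, "fat_pattern") %||% NA,
           fib_pattern = attr(micro, "fib_pattern") %||% NA,
           collagen_modulus = collagen_modulus,
           matrix_model = matrix_model, mesh_nx = mesh$nx,
           mesh_ny = mesh$ny)),
    class = "homog_result"
  )
}

#' @export
print.homog_result <- function(x, ...) {
  cat(sprintf(
    "<homog_result> G*_eff = %.1f + %.1fi Pa at %g Hz (tau = %.3g s)\n",
    x$storage, x$loss, x$frequency, x$tau))
  cat(sprintf("  mesh %d x %d; realized fat %.3f, CPA %.4f\n",
              x$meta$mesh_nx, x$meta$mesh_ny,
              x$meta$realized_fat, x$meta$realized_cpa))
  invisible(x)
}

#' Seeded ensemble of microstructure realizations
#'
#' Generates `n` microstructures with seeds `base_seed, ...,
#' base_seed + n - 1`, homogenizes each, and returns the per-realization
#' table. Geometry, grid and mesh are built once and shared.
#'
#' @param n Number of realizations.
#' @param base_seed First seed.
#' @param fat_target,cpa_target,fat_pattern,fib_pattern Passed to
#'   [build_microstructure()].
#' @param frequency,matrix_model,collagen_modulus,fat_viscosity,lumen_factor
#'   Passed to [homogenize()].
#' @param nx,ny Mesh size.
#' @param grid Optional precomputed [lobule_grid()].
#' @param cell Unit-cell geometry.
#' @param ... Further arguments to [build_microstructure()].
#' @return A tibble of class `homog_ensemble` with one row per realization:
#'   `seed`, `fat_realized`, `cpa_realized`, `storage`, `loss`, `tau`, plus
#'   the shared settings as columns.
#' @export
run_ensemble <- function(n, base_seed = 0, fat_target = 0, cpa_target = 0,
                         fat_pattern = 1, fib_pattern = 1, frequency = 100,
                         matrix_model = material_kelvin_voigt(2000, 0.8),
                         collagen_modulus = 60e3, fat_viscosity = 0.4,
                         lumen_factor = 1e-3, nx = 40, ny = 80,
                         grid = NULL, cell = build_unit_cell(), ...) {
  stopifnot(n >= 1)
  if (is.null(grid)) grid <- lobule_grid(cell)
  mesh <- build_mesh(nx, ny, cell)
  rows <- purrr::map(seq_len(n) - 1L, function(k) {
    seed <- base_seed + k
    micro <- build_microstructure(
      fat_target = fat_target, cpa_target = cpa_target,
      fat_pattern = fat_pattern, fib_pattern = fib_pattern,
      seed = seed, grid = grid, cell = cell, ...)
    res <- homogenize(micro, frequency, matrix_model, collagen_modulus,
                      fat_viscosity, lumen_factor, mesh = mesh)
    tibble::tibble(
      seed = seed,
      fat_target = fat_target, fat_realized = attr(micro, "realized_fat"),
      cpa_target = cpa_target, cpa_realized = attr(micro, "realized_cpa"),
      fat_pattern = fat_pattern, fib_pattern = fib_pattern,
      collagen_G_Pa = collagen_modulus, freq_Hz = frequency,
      mesh_nx = nx, mesh_ny = ny,
      storage = res$storage, loss = res$loss, tau = res$tau)
  })
  as_homog_ensemble(dplyr::bind_rows(rows))
}

#' Voigt--Reuss bounds report for an elastic homogenization result
#'
#' For purely elastic (real) phase moduli, the effective shear modulus must
#' lie between the Reuss (harmonic) and Voigt (arithmetic) mixture bounds
#' computed from the realized phase area fractions.
#'
#' @param G_eff Effective shear modulus (real, Pa).
#' @param phase_moduli Numeric vector of phase moduli (Pa).
#' @param phase_fractions Area fractions (same length, summing to 1).
#' @return A one-row tibble: `reuss`, `voigt`, `value`, `margin_lower`,
#'   `margin_upper`, `within`.
#' @export
bounds_check <- function(G_eff, phase_moduli, phase_fractions) {
  stopifnot(length(phase_moduli) == length(phase_fractions))
  if (abs(sum(phase_fractions) - 1) > 1e-8) {
    stop("phase fractions must sum to 1.", call. = FALSE)
  }
  voigt <- sum(phase_fractions * phase_moduli)
  reuss <- 1 / sum(phase_fractions / phase_moduli)
  tibble::tibble(
    reuss = reuss, voigt = voigt, value = G_eff,
    margin_lower = G_eff - reuss, margin_upper = voigt - G_eff,
    within = G_eff >= reuss - 1e-9 * voigt & G_eff <= voigt + 1e-9 * voigt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
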