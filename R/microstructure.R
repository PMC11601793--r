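#' Build a complete synthetic lobule microstructure
#'
#' Composes the deposition generators into the raster consumed by the
#' homogenizer: collagen is deposited first (if `cpa_target > 0`), then the
#' fat field is generated on the remaining non-collagen parenchyma. When
#' both phases are present the fat target refers to the whole-tissue fat
#' fraction, so the generator target is renormalized by \eqn{1/(1 -
#' \mathrm{CPA})} (fat can only occupy tissue not taken by collagen).
#' Combined microstructures are restricted to CPA <= 10\% (no bridging), the
#' regime where fat and collagen coexist.
#'
#' @param fat_target Overall target mean fat fraction, `[0, 0.4]`.
#' @param cpa_target Target collagen proportionate area, `[0, 0.2]` (`<=
#'   0.1` when `fat_target > 0`).
#' @param fat_pattern,fib_pattern Pattern selectors (1 or 2) for the two
#'   generators.
#' @param seed Integer seed; a single seed drives both generators through
#'   one RNG stream. `NULL` uses the current RNG state.
#' @param grid A [lobule_grid()] tibble; built from `cell` when omitted.
#' @param cell A [build_unit_cell()] object (default 1 mm lobules).
#' @param noise_sigma,profile Passed to [generate_fat_field()].
#' @param ... Passed to [deposit_collagen()] (e.g. `sharpness`).
#' @return A tibble of class `microstructure`: grid columns plus `fat` and
#'   `collagen`; attributes `fat_target`, `realized_fat` (whole-parenchyma
#'   mean including collagen pixels as fat-free), `cpa_target`,
#'   `realized_cpa`, patterns and `seed`.
#' @export
build_microstructure <- function(fat_target = 0, cpa_target = 0,
                                 fat_pattern = 1, fib_pattern = 1,
                                 seed = NULL, grid = NULL,
                                 cell = build_unit_cell(),
                                 noise_sigma = 0.05,
                                 profile = c("sqrt", "linear"), ...) {
  profile <- match.arg(profile)
  if (fat_target > 0 && cpa_target > 0.10) {
    stop("combined steatosis-fibrosis is restricted to CPA <= 0.10 ",
         "(bridging-stage fibrosis is not combined with fat).",
         call. = FALSE)
  }
  if (is.null(grid)) grid <- lobule_grid(cell)
  if (!is.null(seed)) set.seed(seed)

  if (cpa_target > 0) {
    cmask <- deposit_collagen(cpa_target, pattern = fib_pattern, seed = NULL,
                              grid = grid, ...)
    collagen <- cmask$collagen
    realized_cpa <- attr(cmask, "realized_cpa")
    stage_breakdown <- attr(cmask, "stage_breakdown")
  } else {
    collagen <- rep(FALSE, nrow(grid))
    realized_cpa <- 0
    stage_breakdown <- NULL
  }

  parenchyma <- grid$region == "PARENCHYMA"
  if (fat_target > 0) {
    fat_mask <- parenchyma & !collagen
    gen_target <- fat_target / (1 - realized_cpa)
    ff <- generate_fat_field(gen_target, pattern = fat_pattern, seed = NULL,
                             grid = grid, noise_sigma = noise_sigma,
                             profile = profile, mask = fat_mask)
    fat <- ff$fat
  } else {
    fat <- rep(0, nrow(grid))
  }

  out <- grid
  out$fat <- fat
  out$collagen <- collagen
  attr(out, "fat_target") <- fat_target
  attr(out, "realized_fat") <- mean(fat[parenchyma])
  attr(out, "cpa_target") <- cpa_target
  attr(out, "realized_cpa") <- realized_cpa
  attr(out, "stage_breakdown") <- stage_breakdown
  attr(out, "fat_pattern") <- fat_pattern
  attr(out, "fib_pattern") <- fib_pattern
  attr(out, "seed") <- seed
  class(out) <- c("microstructure", class(grid))
  out
}

#' Per-pixel complex shear modulus raster of a microstructure
#'
#' Assigns each pixel its phase modulus at the given frequency: collagen
#' pixels the (purely elastic) collagen modulus, lumen pixels a very soft
#' fraction of the matrix modulus, and parenchyma the fat-adjusted
#' generalized self-consistent modulus.
#'
#' @param micro A `microstructure` tibble (needs `fat`, `collagen`,
#'   `region`).
#' @param matrix_model [material_model] of healthy tissue.
#' @param frequency Frequency, Hz.
#' @param collagen_modulus Elastic collagen shear modulus, Pa.
#' @param fat_viscosity Fat viscosity, Pa s.
#' @param lumen_factor Lumen modulus fraction of the matrix modulus.
#' @return Complex vector of per-pixel moduli (Pa), grid pixel order.
#' @export
modulus_raster <- function(micro,
                           matrix_model = material_kelvin_voigt(2000, 0.8),
                           frequency = 100,
                           collagen_modulus = 60e3,
                           fat_viscosity = 0.4,
                           lumen_factor = 1e-3) {
  G <- fat_to_modulus_field(micro, matrix_model, frequency,
                            fat_viscosity = fat_viscosity,
                            lumen_factor = lumen_factor)
  if (!is.null(micro$collagen)) {
    G[micro$collagen] <- complex(real = collagen_modulus, imaginary = 0)
  }
  G
}
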