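#' Bounded radial coordinate inside a lobule
#'
#' The fat profile is parameterized by position between the lobule boundary
#' and the central vein. The raw ratio "distance-to-boundary over
#' distance-to-centre" is unbounded at the centre, so the bounded surrogate
#' \eqn{\xi = d_{edge} / (d_{edge} + d_{vein})} is used instead: it has the
#' same ordering, equals 0 on the hexagon boundary and approaches 1 at the
#' lobule centre.
#'
#' @param grid A [lobule_grid()] tibble (distance fields required).
#' @return Numeric vector \eqn{\xi \in [0, 1]}, one value per grid pixel.
#' @export
radial_coordinate <- function(grid) {
  denom <- grid$d_edge + grid$d_vein
  grid$d_edge / pmax(denom, 1e-12)
}

#' Radial fat profile
#'
#' Fat fraction as a function of the radial coordinate:
#' \eqn{V(\xi) = V_{out} + \sqrt{\xi}\,(V_{in} - V_{out})} (default), or
#' linear in \eqn{\xi} with `profile = "linear"`. `Vin` is the fraction at
#' the lobule centre, `Vout` at the boundary; Pattern 1 (pericentral fat)
#' has `Vin > Vout`, Pattern 2 (periportal/boundary fat) the reverse.
#'
#' @param xi Radial coordinate(s) in `[0, 1]`.
#' @param Vin,Vout Endpoint fat fractions.
#' @param profile `"sqrt"` (default) or `"linear"`.
#' @return Fat fraction(s).
#' @export
fat_profile <- function(xi, Vin, Vout, profile = c("sqrt", "linear")) {
  profile <- match.arg(profile)
  s <- if (profile == "sqrt") sqrt(xi) else xi
  Vout + s * (Vin - Vout)
}

#' Solve profile endpoints for a target mean fat fraction
#'
#' The parenchyma mean of the noiseless profile is linear in the endpoints,
#' \eqn{\bar V = V_{out}(1 - m) + V_{in} m} with \eqn{m} the parenchyma mean
#' of the profile basis, so the calibration is exact. Pattern 1 fixes
#' `Vout = 0` and solves `Vin`; if the required `Vin` exceeds the 0.5 cap it
#' is clamped and `Vout` is solved instead. Pattern 2 swaps the roles.
#'
#' @param target_mean Target parenchyma-mean fat fraction, in `[0, 0.5]`.
#' @param pattern 1 (pericentral) or 2 (boundary).
#' @param grid A [lobule_grid()] tibble.
#' @param profile Passed to [fat_profile()].
#' @param mask Optional logical vector: pixels over which the mean is taken
#'   (default: parenchyma pixels). Used by the combined steatosis--fibrosis
#'   model to exclude collagen.
#' @return Named numeric vector `c(Vin = , Vout = )`.
#' @export
calibrate_endpoints <- function(target_mean, pattern, grid,
                                profile = c("sqrt", "linear"),
                                mask = NULL) {
  profile <- match.arg(profile)
  if (target_mean < 0 || target_mean > 0.5) {
    stop("`target_mean` must lie in [0, 0.5].", call. = FALSE)
  }
  if (is.null(mask)) mask <- grid$region == "PARENCHYMA"
  xi <- radial_coordinate(grid)[mask]
  m <- mean(if (profile == "sqrt") sqrt(xi) else xi)
  if (pattern == 1) {
    Vin <- target_mean / m
    Vout <- 0
    if (Vin > 0.5) {
      Vin <- 0.5
      Vout <- (target_mean - 0.5 * m) / (1 - m)
    }
  } else {
    Vout <- target_mean / (1 - m)
    Vin <- 0
    if (Vout > 0.5) {
      Vout <- 0.5
      Vin <- (target_mean - 0.5 * (1 - m)) / m
    }
  }
  if (Vin > 0.5 + 1e-12 || Vout > 0.5 + 1e-12 || Vin < 0 || Vout < 0) {
    stop("target mean fat unreachable under the 50% cap.", call. = FALSE)
  }
  c(Vin = Vin, Vout = Vout)
}

#' Generate a synthetic intralobular fat-fraction field
#'
#' Noiseless radial profile calibrated to the target parenchyma mean, plus
#' i.i.d. additive Gaussian pixel noise (standard deviation `noise_sigma` in
#' absolute fat-fraction units, default 0.05), then clipped to `[0, 0.5]`.
#' Lumen pixels carry no fat.
#'
#' @param target_mean Target mean fat fraction over parenchyma, `[0, 0.4]`
#'   in the calibrated range.
#' @param pattern 1 (fat highest at the lobule centre) or 2 (highest at the
#'   boundary).
#' @param seed Integer RNG seed (R's default Mersenne-Twister stream); use
#'   `NULL` to draw from the current RNG state.
#' @param grid A [lobule_grid()] tibble.
#' @param noise_sigma Noise standard deviation in fat-fraction units.
#' @param profile Radial profile form, see [fat_profile()].
#' @param mask Optional logical vector of pixels eligible for fat (default
#'   parenchyma); ineligible pixels get 0.
#' @return A tibble of class `fat_field`: the grid plus a `fat` column;
#'   attributes `target_mean`, `realized_mean`, `Vin`, `Vout`, `pattern`,
#'   `noise_sigma`, `seed`, `profile`.
#' @export
generate_fat_field <- function(target_mean, pattern = 1, seed = NULL,
                               grid, noise_sigma = 0.05,
                               profile = c("sqrt", "linear"),
                               mask = NULL) {
  profile <- match.arg(profile)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mask)) mask <- grid$region == "PARENCHYMA"
  ends <- calibrate_endpoints(target_mean, pattern, grid, profile, mask)
  xi <- radial_coordinate(grid)
  V <- fat_profile(xi, ends["Vin"], ends["Vout"], profile)
  if (noise_sigma > 0 && target_mean > 0) {
    # a fat-free lobule has nothing to speckle; clipping half-normal noise
    # at zero would otherwise bias the mean upward
    V[mask] <- V[mask] + stats::rnorm(sum(mask), 0, noise_sigma)
  }
  V <- pmin(pmax(V, 0), 0.5)
  V[!mask] <- 0
  out <- grid
  out$fat <- V
  attr(out, "target_mean") <- target_mean
  attr(out, "realized_mean") <- mean(V[mask])
  attr(out, "Vin") <- unname(ends["Vin"])
  attr(out, "Vout") <- unname(ends["Vout"])
  attr(out, "pattern") <- pattern
  attr(out, "noise_sigma") <- noise_sigma
  attr(out, "seed") <- seed
  attr(out, "profile") <- profile
  class(out) <- c("fat_field", class(grid))
  out
}

#' Map a fat field to a per-pixel complex modulus raster
#'
#' Each parenchyma pixel gets the generalized self-consistent effective
#' modulus [effective_fat_modulus()] for its local fat fraction; lumen
#' pixels get `lumen_factor` times the matrix modulus (a very soft inclusion
#' that keeps the finite-element operator nonsingular).
#'
#' @param fat A `fat_field` (or any grid tibble with `fat` and `region`).
#' @param matrix_model [material_model] of the healthy tissue matrix.
#' @param frequency Frequency, Hz.
#' @param fat_viscosity Newtonian fat viscosity, Pa s (fat modulus
#'   \eqn{i\omega\eta}).
#' @param lumen_factor Lumen modulus as a fraction of the matrix modulus.
#' @return Complex vector of per-pixel shear moduli (Pa), pixel order as in
#'   the grid.
#' @export
fat_to_modulus_field <- function(fat, matrix_model, frequency,
                                 fat_viscosity = 0.4, lumen_factor = 1e-3) {
  Gm <- complex_modulus(matrix_model, frequency)
  Gf <- complex(real = 0, imaginary = 2 * pi * frequency * fat_viscosity)
  G <- effective_fat_modulus(fat$fat, Gm, Gf)
  lumen <- fat$region != "PARENCHYMA"
  G[lumen] <- lumen_factor * Gm
  G
}
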