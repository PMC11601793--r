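#' Material models for tissue phases
#'
#' Constructors for the frequency-domain shear rheologies used in the
#' framework. All moduli are in Pa, viscosities in Pa s, frequencies in Hz
#' (angular frequency \eqn{\omega = 2\pi f}).
#'
#' * `material_elastic(G0)`: \eqn{G^*(\omega) = G_0}.
#' * `material_kelvin_voigt(G0, eta)`: \eqn{G^*(\omega) = G_0 + i\omega\eta}.
#' * `material_springpot(coef, alpha)`: power-law (springpot)
#'   \eqn{G^*(\omega) = c\,(i\omega)^a}, \eqn{0 \le a < 1}; units of `coef`
#'   are Pa s^a.
#'
#' Defaults elsewhere in the package follow the healthy-liver calibration:
#' Kelvin--Voigt matrix with \eqn{G_0 = 2} kPa, \eqn{\eta = 0.8} Pa s; fat as
#' a purely viscous (Newtonian) phase with \eqn{\eta = 0.4} Pa s; collagen
#' purely elastic at 60--300 kPa.
#'
#' @param G0 Shear modulus, Pa.
#' @param eta Viscosity, Pa s.
#' @param coef Springpot coefficient, Pa s^a.
#' @param alpha Springpot power, in `[0, 1)`.
#' @return An object of class `material_model`.
#' @examples
#' complex_modulus(material_kelvin_voigt(2000, 0.8), 100)  # 2000 + 502.7i
#' @name material_model
NULL

new_material <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "material_model")
}

#' @rdname material_model
#' @export
material_elastic <- function(G0) {
  stopifnot(is.numeric(G0), G0 >= 0)
  new_material("ELASTIC", list(G0 = G0))
}

#' @rdname material_model
#' @export
material_kelvin_voigt <- function(G0, eta) {
  stopifnot(is.numeric(G0), G0 >= 0, is.numeric(eta), eta >= 0)
  new_material("KELVIN_VOIGT", list(G0 = G0, eta = eta))
}

#' @rdname material_model
#' @export
material_springpot <- function(coef, alpha) {
  stopifnot(is.numeric(coef), coef >= 0, is.numeric(alpha),
            alpha >= 0, alpha < 1)
  new_material("SPRINGPOT", list(coef = coef, alpha = alpha))
}

#' @export
print.material_model <- function(x, ...) {
  p <- x$params
  desc <- switch(x$kind,
    ELASTIC = sprintf("elastic, G0 = %g Pa", p$G0),
    KELVIN_VOIGT = sprintf("Kelvin-Voigt, G0 = %g Pa, eta = %g Pa s",
                           p$G0, p$eta),
    SPRINGPOT = sprintf("springpot, c = %g Pa s^a, a = %g", p$coef, p$alpha))
  cat("<material_model>", desc, "\n")
  invisible(x)
}

#' Complex shear modulus of a material at a frequency
#'
#' @param model A [material_model] object.
#' @param frequency Frequency in Hz (> 0).
#' @return A complex scalar \eqn{G' + iG''} in Pa.
#' @export
complex_modulus <- function(model, frequency) {
  stopifnot(inherits(model, "material_model"))
  if (!is.numeric(frequency) || any(frequency <= 0)) {
    stop("`frequency` must be positive (Hz).", call. = FALSE)
  }
  w <- 2 * pi * frequency
  p <- model$params
  switch(model$kind,
    ELASTIC = complex(real = p$G0, imaginary = 0) + 0 * w,
    KELVIN_VOIGT = complex(real = p$G0, imaginary = w * p$eta),
    SPRINGPOT = p$coef * w^p$alpha *
      complex(real = cos(p$alpha * pi / 2), imaginary = sin(p$alpha * pi / 2))
  )
}

#' Material model from a config list
#'
#' Accepts a list like `list(kind = "KELVIN_VOIGT", G0 = 2000, eta = 0.8)`
#' (e.g. parsed from a JSON/YAML config block).
#'
#' @param x A named list with `kind` and the model's parameters.
#' @return A [material_model] object.
#' @export
material_from_config <- function(x) {
  kind <- toupper(x$kind)
  switch(kind,
    ELASTIC = material_elastic(x$G0),
    KELVIN_VOIGT = material_kelvin_voigt(x$G0, x$eta),
    SPRINGPOT = material_springpot(x$coef, x$alpha),
    stop("unknown material kind: ", kind, call. = FALSE))
}

# Christensen-Lo generalized self-consistent quadratic coefficients for the
# effective shear modulus of a matrix with spherical inclusions.
# mr = G_inclusion / G_matrix (may be complex), c = volume fraction,
# nu_i / nu_m = phase Poisson ratios. Returns list(A, B, C) of the quadratic
# A r^2 + B r + C = 0 in r = G_eff / G_matrix.
gscm_coefficients <- function(mr, c, nu_i, nu_m) {
  e1 <- (mr - 1) * (49 - 50 * nu_i * nu_m) + 35 * mr * (nu_i - 2 * nu_m) +
    35 * (2 * nu_i - nu_m)
  e2 <- (mr - 1) * (7 + 5 * nu_i) + 35 * (1 - nu_i)
  e3 <- (mr - 1) * (8 - 10 * nu_m) + 15 * (1 - nu_m)
  c13 <- c^(1 / 3)
  A <- 8 * (mr - 1) * (4 - 5 * nu_m) * e1 * c13^10 -
    2 * (63 * (mr - 1) * e2 + 2 * e1 * e3) * c13^7 +
    252 * (mr - 1) * e2 * c13^5 -
    50 * (mr - 1) * (7 - 12 * nu_m + 8 * nu_m^2) * e2 * c +
    4 * (7 - 10 * nu_m) * e2 * e3
  B <- -4 * (mr - 1) * (1 - 5 * nu_m) * e1 * c13^10 +
    4 * (63 * (mr - 1) * e2 + 2 * e1 * e3) * c13^7 -
    504 * (mr - 1) * e2 * c13^5 +
    150 * (mr - 1) * (3 - nu_m) * nu_m * e2 * c +
    3 * (15 * nu_m - 7) * e2 * e3
  C <- 4 * (mr - 1) * (5 * nu_m - 7) * e1 * c13^10 -
    2 * (63 * (mr - 1) * e2 + 2 * e1 * e3) * c13^7 +
    252 * (mr - 1) * e2 * c13^5 +
    25 * (mr - 1) * (nu_m^2 - 7) * e2 * c -
    (7 + 5 * nu_m) * e2 * e3
  list(A = A, B = B, C = C)
}

#' Effective complex shear modulus of fat-laden tissue
#'
#' Generalized self-consistent (three-phase composite-sphere,
#' Christensen--Lo) estimate for spherical fat inclusions at volume fraction
#' `phi` in a tissue matrix, with both phases incompressible (Poisson ratio
#' 1/2) and complex moduli handled through the elastic--viscoelastic
#' correspondence principle. Of the two roots of the quadratic in
#' \eqn{G_{\mathrm{eff}}/G_m}, the physical branch is the one continuous
#' with the dilute limit
#' \eqn{G_m\,[1 + 5\phi (G_i - G_m)/(3G_m + 2G_i)]} as \eqn{\phi \to 0}.
#'
#' The scheme (and the histological picture of discrete droplets) is only
#' trusted up to 50\% local fat, hence the hard cap on `phi`.
#'
#' @param phi Fat volume fraction(s), in `[0, 0.5]`. Vectorized.
#' @param G_matrix Complex shear modulus of the tissue matrix, Pa.
#' @param G_fat Complex shear modulus of the fat phase, Pa.
#' @param nu_inclusion,nu_matrix Phase Poisson ratios (default 1/2,
#'   incompressible).
#' @return Complex vector of effective shear moduli, Pa.
#' @export
effective_fat_modulus <- function(phi, G_matrix, G_fat,
                                  nu_inclusion = 0.5, nu_matrix = 0.5) {
  if (any(phi < 0 | phi > 0.5)) {
    stop("`phi` must lie in [0, 0.5] (50% local fat cap).", call. = FALSE)
  }
  Gm <- as.complex(G_matrix)
  Gi <- as.complex(G_fat)
  mr <- Gi / Gm
  out <- rep(Gm, length(phi))
  active <- phi > 0 & abs(mr - 1) > 1e-14
  if (!any(active)) return(out)
  cf <- phi[active]
  co <- gscm_coefficients(mr, cf, nu_inclusion, nu_matrix)
  disc <- sqrt(co$B^2 - 4 * co$A * co$C)
  r1 <- (-co$B + disc) / (2 * co$A)
  r2 <- (-co$B - disc) / (2 * co$A)
  dilute <- 1 + 5 * cf * (Gi - Gm) / (3 * Gm + 2 * Gi)
  pick1 <- abs(r1 - dilute) <= abs(r2 - dilute)
  out[active] <- ifelse(pick1, r1, r2) * Gm
  out
}

#' Relaxation time of a complex modulus
#'
#' \eqn{\tau = G'' / (\omega G')}, the effective viscosity-to-elasticity
#' ratio at angular frequency \eqn{\omega = 2\pi f}. For a Kelvin--Voigt
#' material this recovers \eqn{\eta / G_0} at every frequency.
#'
#' @param G Complex shear modulus (Pa), vectorized.
#' @param frequency Frequency in Hz.
#' @return Relaxation time(s) in seconds.
#' @export
relaxation_time <- function(G, frequency) {
  if (any(Re(G) <= 0)) {
    stop("relaxation time undefined for non-positive storage modulus.",
         call. = FALSE)
  }
  Im(G) / (2 * pi * frequency * Re(G))
}
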