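#' Collagen deposition probability
#'
#' Probability that a pixel at distance `x` (mm) from the stage's reference
#' structure receives collagen: \eqn{P = 1 - \Phi((k x / d - \mu)/\sigma)}
#' with \eqn{\Phi} the standard normal CDF. The probability decays with
#' distance, so deposition concentrates around the reference structure; `d`
#' controls the spread (larger `d`, wider deposition) and the dimensionless
#' sharpness `k` rescales `x/d` so that patterns are visually localized at
#' the lobule scale.
#'
#' @param x Distance(s) from the reference structure, mm (>= 0).
#' @param d Spread control parameter, mm (> 0).
#' @param mu,sigma Normal CDF location and scale (defaults 2 and 10).
#' @param sharpness Dimensionless factor multiplying `x/d` (default 20).
#' @return Probability vector in (0, 1).
#' @export
deposition_probability <- function(x, d, mu = 2, sigma = 10, sharpness = 20) {
  if (any(d <= 0)) stop("`d` must be positive.", call. = FALSE)
  1 - stats::pnorm((sharpness * x / d - mu) / sigma)
}

# CPA -> spread parameter interpolation tables (mm), clamped outside
stage_d_tables <- list(
  PERISINUSOIDAL = list(cpa = c(0.01, 0.05), d = c(0.75, 1.4)),
  PERIPORTAL = list(cpa = c(0.05, 0.10), d = c(0.75, 1.75)),
  BRIDGING = list(cpa = c(0.10, 0.20), d = c(0.5, 1.0))
)

stage_spread <- function(stage, cpa_cum) {
  tb <- stage_d_tables[[stage]]
  stats::approx(tb$cpa, tb$d, xout = cpa_cum, rule = 2)$y
}

#' Staged deposition plan for a target CPA
#'
#' Fibrosis progresses in stages: up to 5\% CPA deposition is perisinusoidal
#' (referenced to the central veins), the portion between 5\% and 10\% is
#' periportal (referenced to the portal triads), and anything beyond 10\% is
#' bridging (referenced to hexagon edges in Pattern 1, portal-to-central
#' radii in Pattern 2). Each stage's spread parameter `d` is linearly
#' interpolated in the cumulative CPA reached at the end of that stage.
#'
#' @param target_cpa Target collagen proportionate area, `[0, 0.2]`.
#' @return A tibble with columns `stage`, `stage_cpa`, `cpa_cum`, `d`.
#' @export
stage_plan <- function(target_cpa) {
  if (target_cpa < 0 || target_cpa > 0.2) {
    stop("`target_cpa` must lie in [0, 0.2] (calibrated range).",
         call. = FALSE)
  }
  portions <- c(
    PERISINUSOIDAL = min(target_cpa, 0.05),
    PERIPORTAL = min(max(target_cpa - 0.05, 0), 0.05),
    BRIDGING = max(target_cpa - 0.10, 0)
  )
  keep <- portions > 0
  stages <- names(portions)[keep]
  cpa_cum <- cumsum(portions)[keep]
  tibble::tibble(
    stage = stages,
    stage_cpa = unname(portions[keep]),
    cpa_cum = unname(cpa_cum),
    d = vapply(seq_along(stages),
               function(k) stage_spread(stages[k], cpa_cum[k]), numeric(1))
  )
}

#' Deposit collagen on the lobule grid
#'
#' Probabilistic staged deposition: for each stage in the [stage_plan()],
#' undeposited parenchyma pixels are repeatedly swept with Bernoulli trials
#' at the stage's [deposition_probability()] (using the stage's distance
#' field) until the stage's pixel-count quota is met; a final partial sweep
#' subsamples its successes uniformly so the realized CPA is exact to one
#' pixel. Deterministic given `seed`. Lumen pixels never receive collagen.
#'
#' Pattern 1 bridges portal-to-portal (edge distance field); Pattern 2
#' bridges portal-to-central (radius field). The two patterns share the
#' perisinusoidal and periportal stages, so masks at CPA <= 10\% are
#' identical across patterns for the same seed.
#'
#' @param target_cpa Target collagen proportionate area, `[0, 0.2]`.
#' @param pattern 1 or 2 (bridging geometry).
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @param grid A [lobule_grid()] tibble.
#' @param mu,sigma,sharpness Passed to [deposition_probability()].
#' @param denominator `"cell"` (default: CPA is collagen pixels over all
#'   cell pixels) or `"parenchyma"`.
#' @return A tibble of class `collagen_mask`: the grid plus a logical
#'   `collagen` column; attributes `target_cpa`, `realized_cpa`,
#'   `stage_breakdown`, `pattern`, `seed`.
#' @export
deposit_collagen <- function(target_cpa, pattern = 1, seed = NULL, grid,
                             mu = 2, sigma = 10, sharpness = 20,
                             denominator = c("cell", "parenchyma")) {
  denominator <- match.arg(denominator)
  if (!is.null(seed)) set.seed(seed)
  plan <- stage_plan(target_cpa)
  n_total <- if (denominator == "cell") nrow(grid) else
    sum(grid$region == "PARENCHYMA")
  parenchyma <- grid$region == "PARENCHYMA"
  mask <- rep(FALSE, nrow(grid))
  stage_counts <- c(PERISINUSOIDAL = 0L, PERIPORTAL = 0L, BRIDGING = 0L)
  quota_cum <- round(plan$cpa_cum * n_total)
  for (k in seq_len(nrow(plan))) {
    stage <- plan$stage[k]
    field <- switch(stage,
      PERISINUSOIDAL = grid$d_vein,
      PERIPORTAL = grid$d_triad,
      BRIDGING = if (pattern == 1) grid$d_edge else grid$d_radius)
    P <- deposition_probability(field, plan$d[k], mu, sigma, sharpness)
    need <- quota_cum[k] - sum(mask)
    while (need > 0) {
      avail <- which(parenchyma & !mask)
      if (length(avail) == 0L) {
        stop("collagen quota unreachable: no undeposited parenchyma left.",
             call. = FALSE)
      }
      hits <- avail[stats::runif(length(avail)) < P[avail]]
      if (length(hits) > need) {
        hits <- sample(hits, need)
      }
      mask[hits] <- TRUE
      stage_counts[stage] <- stage_counts[stage] + length(hits)
      need <- need - length(hits)
    }
  }
  out <- grid
  out$collagen <- mask
  attr(out, "target_cpa") <- target_cpa
  attr(out, "realized_cpa") <- sum(mask) / n_total
  attr(out, "stage_breakdown") <- stage_counts / n_total
  attr(out, "pattern") <- pattern
  attr(out, "seed") <- seed
  class(out) <- c("collagen_mask", class(grid))
  out
}

#' Collagen proportionate area of a mask
#'
#' Collagen pixel count over the total cell pixel count (the conventional
#' whole-section denominator; set `denominator = "parenchyma"` to exclude
#' lumens).
#'
#' @param mask A `collagen_mask` tibble (or any grid with a logical
#'   `collagen` column).
#' @param denominator `"cell"` or `"parenchyma"`.
#' @return CPA as a fraction.
#' @export
cpa <- function(mask, denominator = c("cell", "parenchyma")) {
  denominator <- match.arg(denominator)
  n <- if (denominator == "cell") nrow(mask) else
    sum(mask$region == "PARENCHYMA")
  sum(mask$collagen) / n
}
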