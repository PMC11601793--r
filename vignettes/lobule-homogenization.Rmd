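---
title: "Homogenized viscoelasticity of fatty and fibrotic lobule microstructures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homogenized viscoelasticity of fatty and fibrotic lobule microstructures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(lobulemech)
```

## The model

Wave-based elastography (ultrasound shear-wave and MR elastography, roughly
50–300 Hz) measures the bulk complex shear modulus of liver tissue,
$G^*(\omega) = G'(\omega) + iG''(\omega)$. lobulemech asks how that bulk
modulus emerges from the microstructure of the hepatic lobule — the ~1 mm
hexagonal tissue unit with a central vein at its centre and portal triads at
its vertices — as fat (steatosis) and collagen (fibrosis) accumulate.

The tissue is idealized as a perfectly periodic 2D tiling of identical
lobules. The smallest rectangular cell of that tiling consists of four
half-hexagons: for a 1 mm (vertex-to-vertex) lobule it measures
$\sqrt{3}/2 \times 1.5$ mm and contains exactly two lobules. Because liver
tissue is nearly incompressible, only the shear response is informative, and
because elastography wavelengths (> 3 mm) are large compared to the lobule,
inertia and wave scattering inside the cell are neglected: the bulk modulus
follows from an elastostatic periodic-cell computation at each frequency.

The homogenization itself is the classical two-scale (asymptotic-expansion)
construction: impose a unit macroscopic engineering shear
$\gamma_{12} = 1$ as an eigenstrain, solve for the periodic fluctuation
displacement on the cell,

$$\nabla\cdot\sigma = 0,\qquad
  \sigma(\omega) = E(\omega)\,(\varepsilon(v) + \varepsilon^0),\qquad
  v_{\text{right}} = v_{\text{left}},\; v_{\text{top}} = v_{\text{bottom}},$$

and read off the homogenized modulus as the volume-averaged stress,
$G^*_{\text{eff}} = \langle\sigma_{12}\rangle$. With this normalization a
homogeneous cell returns its phase modulus exactly (the patch test in the
test suite). The effective relaxation time
$\tau = G''_{\text{eff}} / (\omega\, G'_{\text{eff}})$ condenses the result
into an elasticity measure and a relative-viscosity measure.

## Phase rheologies

All moduli are handled in Pa internally.

* **Healthy matrix** — Kelvin–Voigt, $G^* = G_0 + i\omega\eta$, with
  $G_0 = 2$ kPa and $\eta = 0.8$ Pa s (so $2.0 + 0.503i$ kPa at 100 Hz).
  The combined steatosis–fibrosis study instead uses a power-law
  (springpot) matrix $G^* = c\,(i\omega)^a$ with $c = 800$ (Pa s$^a$) and
  $a = 0.15$, giving a 0.49 kPa loss modulus at 100 Hz.
* **Fat** — a Newtonian fluid, $G^* = i\omega\eta_f$ with $\eta_f = 0.4$
  Pa s ($0.25i$ kPa at 100 Hz). One published account quotes $0.5i$ kPa at
  100 Hz for the same viscosity; that value is inconsistent with
  $i\omega\eta$ and the package keeps the formula.
* **Collagen** — purely elastic, 60 kPa by default, studied over 60–300 kPa.
* **Lumens** (central vein, portal triads) — not holes but very soft
  inclusions at $10^{-3}\times$ the matrix modulus, which keeps the
  operator nonsingular while contributing essentially no stiffness. Their
  radii are not histological measurements; the defaults (0.05 and 0.04 mm)
  are calibration knobs chosen at typical histological scale.

Fat lives inside hepatocytes at a scale far below the material grid, so a
pixel's fat fraction $\phi$ is converted to a local modulus analytically
with the generalized self-consistent (three-phase composite-sphere,
Christensen–Lo) scheme for spherical inclusions, specialized to
incompressible phases and extended to complex moduli by the
elastic–viscoelastic correspondence principle. The scheme is a quadratic in
$G_{\text{eff}}/G_m$; the package selects the root continuous with the
dilute limit $G_m[1 + 5\phi(G_i - G_m)/(3G_m + 2G_i)]$, verified by a
continuity scan and a dilute-expansion oracle in the tests. The scheme (and
the droplet picture) is only trusted to $\phi = 0.5$, which is why local
fat is hard-capped at 50%. Collagen, by contrast, is deposited at a scale
comparable to the grid and enters the computational model directly as a
binary phase.

```{r rheology}
complex_modulus(material_kelvin_voigt(2000, 0.8), 100)
effective_fat_modulus(0.3, 2000 + 502.7i, 251.3i)
```

## Synthetic microstructures

All inputs are generated; there is no external data. The carrier is an
80×160 raster of pixel centres over the unit cell with precomputed periodic
distance fields: to the nearest central vein, nearest portal triad, nearest
hexagon edge, and nearest centre-to-vertex radius.

**Steatosis.** The fat fraction follows a radial profile
$V(\xi) = V_{out} + \sqrt{\xi}\,(V_{in} - V_{out})$ in the bounded
coordinate $\xi = d_{\text{edge}} / (d_{\text{edge}} + d_{\text{vein}})$
($\xi = 0$ on the lobule boundary, $\to 1$ at the centre; the raw
boundary-to-centre distance ratio is unbounded at the centre, so this
surrogate with identical ordering is used). Pattern 1 peaks at the centre
(pericentral/zone-3 fat, the common presentation), Pattern 2 at the
boundary. Because the parenchyma mean is linear in $(V_{in}, V_{out})$ the
endpoints solve exactly for any target mean; if the free endpoint would
exceed the 50% cap it is clamped and the other endpoint takes over. On top
of the profile each parenchyma pixel receives i.i.d. Gaussian noise with
$\sigma = 0.05$ in absolute fat-fraction units — relative noise would
vanish where $V = 0$ and produce an implausibly clean lobule rim — and the
field is then clipped to $[0, 0.5]$ (noise-then-clip). The clip introduces
a small positive bias at low $V$; the tests verify the realized mean stays
within ±0.01 of the target. A zero-fat target produces an exactly zero
field. `profile = "linear"` switches to a profile linear in $\xi$.

**Fibrosis.** Collagen deposition is staged the way fibrosis progresses:
the first 5% CPA (collagen proportionate area) is perisinusoidal and keyed
to the distance from the nearest central vein; the portion between 5% and
10% is periportal, keyed to the nearest portal triad; anything beyond 10%
is bridging — along hexagon edges for portal-to-portal septa (Pattern 1)
or along the centre-to-vertex radii for portal-to-central septa
(Pattern 2). Each stage deposits on undeposited parenchyma pixels by
Bernoulli sweeps with probability
$P = 1 - \Phi\big((k\,x/d - \mu)/\sigma\big)$, decreasing in the distance
$x$; $d$ is linearly interpolated in cumulative CPA from the calibrated
tables (perisinusoidal 0.75 mm @ 1% → 1.4 mm @ 5%; periportal 0.75 @ 5% →
1.75 @ 10%; bridging 0.5 @ 10% → 1.0 @ 20%). As printed, the cumulative
normal with $\mu = 2$, $\sigma = 10$ *increases* with distance and is
nearly flat over a 1 mm cell; the package therefore (a) uses the
complement so deposition concentrates around the reference structure, and
(b) multiplies $x/d$ by a dimensionless sharpness $k = 20$ so the patterns
are visually localized. $\mu$, $\sigma$ and $k$ are all exposed. Stage
quotas are enforced by pixel count, so the realized CPA is exact to one
pixel, and stages only ever add pixels: masks at 5% CPA are subsets of
masks at 10% with the same seed, and the two patterns are identical up to
10% CPA. CPA is counted against the whole cell area by default
(`denominator = "parenchyma"` is available).

**Combined.** Collagen is deposited first (restricted to CPA ≤ 10%:
advanced fibrosis is accompanied by fat loss, so bridging is never
combined with fat), then the fat field is generated on the remaining
parenchyma with its target divided by $1 - \text{CPA}$, since the overall
fat fraction refers to tissue that collagen has not displaced.

```{r micro}
micro <- build_microstructure(fat_target = 0.16, cpa_target = 0.08, seed = 1)
attributes(micro)[c("realized_fat", "realized_cpa")]
```

## Discretization and solver

The cell is meshed with a structured 40×80 grid of 8-node serendipity
quadrilaterals (QUAD8) under plane strain, with 2×2 Gauss quadrature;
material values at Gauss points are nearest-pixel lookups on the 80×160
raster (at 40×80 each element covers a 2×2 pixel block and each Gauss
point lands nearest a distinct pixel, so every pixel is sampled exactly
once). Periodicity is imposed by a master–slave reduction (right→left,
top→bottom, the four corners to one master) and the remaining rigid
translation is removed by pinning one master node; eigenstrain loads are
self-equilibrated, so the pin carries no reaction.

Near-incompressibility is modelled with $\nu = 0.4999$ and *selective
reduced integration*: the deviatoric part of the constitutive matrix is
integrated at the 2×2 points, the volumetric part at the element centroid
only, with the element volumetric modulus
$\lambda = \tfrac{2\nu}{1-2\nu}\,\bar G$ built from the element-mean shear
modulus. Full 2×2 integration of the volumetric term visibly over-stiffens
elements whose four Gauss points straddle the binary tissue/collagen
contrast and roughly doubles the 40×80-vs-80×160 discrepancy on fibrotic
cells; SRI removes the artificial constraint while leaving the homogeneous
patch test and the laminate (harmonic-mean) oracle exact to solver
tolerance. Both $\nu$ and the mesh size are arguments.

The discrete system is complex-symmetric,
$K = K' + iK''$ with $K'$ SPD. No complex sparse factorization is
available in the R ecosystem used here, so the production solver factors
$K'$ once (supernodal Cholesky) and resolves the loss coupling by the
fixed-point iteration $K'u_r = f_r + K''u_i$, $K'u_i = f_i - K''u_r$,
which contracts at the maximum local loss ratio
$\sup G''/G' \approx 0.25{-}0.65$ for these tissues (relative residual
tolerance $10^{-10}$, typically 15–20 iterations). If the iteration
stalls before $10^{-8}$ the solver falls back to a sparse LU of the exact
real block form $[[K', -K''], [K'', K']]$; that block form is also kept as
an independent route for the parity test against dense complex
arithmetic.

```{r homog}
res <- homogenize(micro, frequency = 100)
res
tidy(res)
```

## Ensembles, studies and problem sizes

Deposition is random, so bulk properties are reported as seeded-ensemble
means; `run_ensemble()` uses consecutive seeds so any row of any sweep is
replayable bit-for-bit from its seed. The stock studies are
`sweep_steatosis()` (fat 0–40%, both patterns, 100 Hz),
`sweep_fibrosis()` (CPA 1–20%, collagen 60–300 kPa, both patterns),
`sweep_combined()` (fat 0–30% × CPA 1–10%, springpot matrix, 100 and
300 Hz) and `convergence_check()` (40×80 vs 80×160 ensemble means for 20%
fat, 10% CPA, and 15% fat + 10% CPA).

The reference studies behind these settings used 300 (steatosis) and 100
(fibrosis) realizations; the package defaults to desk-scale ensembles
(`n_per = 10`, 25 for convergence checks, 100 for the fibrosis reference
level), sizes chosen so the full test suite and the acceptance script
re-run the studies end-to-end in minutes on one core. Ensemble-mean
standard errors at these sizes are well under the effects being measured
(the fibrosis ensemble standard deviation at 10% CPA is ~15 Pa on a
~2.3 kPa mean).

## What the generators do and do not emulate

The generators reproduce the *spatial organization* seen in histology —
zonal fat gradients with droplet-scale randomness, staged
perisinusoidal/periportal/bridging collagen with CPA-controlled spread —
but not droplet geometry, macro/micro-vesicular distinction, spatially
correlated noise, fiber orientation, or septa thickness statistics.
Passing tests therefore demonstrate that the *pipeline* (generation →
composite theory → periodic viscoelastic homogenization) behaves
correctly and reproduces the qualitative disease signatures: storage
modulus falls and relaxation time rises with fat; storage rises and
relaxation time falls with CPA; pattern effects are negligible for fat but
significant for bridging-stage collagen. They do not validate the
generators against real histology.

One quantitative limitation deserves emphasis. Per-pixel Bernoulli
deposition produces spatially uncorrelated collagen speckle. Speckle
maximizes within-element material contrast, which (a) keeps the effective
stiffening of 10% CPA at 60 kPa collagen near the dispersed-inclusion
level (~2.3 kPa ensemble mean at 100 Hz, where the reference computation
reports ~4.1 kPa, a level that implies partially connected collagen
structures), and (b) leaves a ~2.4% 40×80-vs-80×160 ensemble-mean
difference for fibrotic cells where the reference reports 0.89%. With the
printed probability parameters the deposition field is nearly flat, and no
parameterization of the per-pixel rule reproduces both the visual
localization and those reference levels; a clustered (correlated)
deposition process would be required. The probability parameters are
exposed (`mu`, `sigma`, `sharpness`) but their defaults are fixed study
conditions, not fitting knobs.

## Numerical choices and degenerate inputs

* Quadratic-root selection in the composite-sphere scheme: the root
  nearest the dilute estimate; at $\phi = 0$ the matrix modulus is
  returned identically, and equal phase moduli short-circuit to the
  matrix.
* $\xi$ is guarded by $\varepsilon = 10^{-12}$ in the denominator; the
  80×160 raster never triggers the guard.
* Stage quotas round to whole pixels; a zero CPA target yields an empty
  plan, and an unreachable quota (no parenchyma left) is an error rather
  than a silent shortfall.
* Lumen radii of zero are legal (an all-parenchyma cell); lumen pixels are
  excluded from fat accounting and collagen deposition.
* `vein_radius`/`triad_radius` must stay below a quarter lobule diameter
  so lumens cannot merge.
* Meshes must be at least 2×2; the default pairing 40×80 ↔ 80×160 pixel
  grid keeps the Gauss-point/pixel alignment described above.
* Noise, deposition and ensemble seeding all run through R's default
  Mersenne–Twister stream; a `build_microstructure()` seed drives collagen
  first, then fat, through one stream.

## Session info

```{r session}
sessionInfo()
```
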