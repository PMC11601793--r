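# lobulemech

Micromechanical homogenization of hepatic lobule microstructures: from
synthetic histology (fat and collagen deposition) to the bulk complex shear
modulus that elastography measures.

## Who this is for

Elastography (ultrasound shear-wave, MR elastography) reads out liver
stiffness and viscosity at 50–300 Hz as biomarkers for steatosis (MASLD),
steatohepatitis (MASH) and fibrosis. The missing link is quantitative:
*how much* should a given fat fraction or collagen proportionate area (CPA)
change the storage modulus G′, the loss modulus G″, or the relaxation time
τ = G″/(ωG′)? `lobulemech` answers that with a hybrid
analytical–computational pipeline on the periodic unit cell of the liver
lattice, for researchers modeling tissue viscoelasticity or interpreting
elastography biomarkers.

## The model in one paragraph

Liver tissue is idealized as a periodic tiling of 1 mm hexagonal lobules
(central vein at the centre, portal triads at the vertices); the repeating
rectangular cell (√3/2 × 1.5 mm, two lobules, built from four
half-hexagons) carries an 80×160 material raster. Steatosis is generated as
a radial fat-fraction profile V(ξ) = V_out + √ξ(V_in − V_out) with 5%
absolute Gaussian pixel noise, capped at 50%; each pixel's fat fraction is
converted to a local complex shear modulus with the generalized
self-consistent composite-sphere (Christensen–Lo) scheme for incompressible
phases. Fibrosis is deposited as a binary collagen mask by a staged
probabilistic rule (perisinusoidal ≤ 5% CPA → periportal ≤ 10% → bridging,
with P = 1 − Φ((k·x/d − μ)/σ) decaying with distance x from each stage's
reference structure). The frequency-domain viscoelastic cell problem
σ = E(ω)(ε(v) + ε⁰) with periodic boundary conditions and unit macroscopic
shear γ₁₂ = 1 is then solved with plane-strain QUAD8 finite elements
(selective reduced integration, ν = 0.4999), and the homogenized modulus is
the volume-averaged stress: G*_eff = ⟨σ₁₂⟩.

## Worked example

```r
library(lobulemech)

# healthy matrix: Kelvin-Voigt 2 kPa + 0.8 Pa s at 100 Hz
complex_modulus(material_kelvin_voigt(2000, 0.8), 100)
#> [1] 2000+502.655i

# a MASH-like lobule: 16% fat (pericentral) on top of 8% CPA collagen
micro <- build_microstructure(fat_target = 0.16, cpa_target = 0.08, seed = 1)
res <- homogenize(micro, frequency = 100)
res
#> <homog_result> G*_eff = 1610.5 + 521.6i Pa at 100 Hz (tau = 0.000515 s)
#>   mesh 40 x 80; realized fat 0.161, CPA 0.0800
tidy(res)
#> # A tibble: 1 x 9
#>   storage  loss      tau freq_Hz fat_realized cpa_realized collagen_G_Pa ...
#>     <dbl> <dbl>    <dbl>   <dbl>        <dbl>        <dbl>         <dbl>
#> 1   1611.  522. 0.000515     100        0.161       0.0800         60000
```

The fat softened the tissue well below its healthy 2 kPa while the
collagen partly compensated, and the relaxation time rose from the healthy
0.4 ms to 0.52 ms — exactly the competition that makes single-frequency
elastography ambiguous for combined disease.

Ensembles and sweeps return tibbles ready for dplyr/ggplot2:

```r
sw <- sweep_steatosis(fat_targets = c(0, 0.2, 0.4), n_per = 5)
glance(sw)          # per-setting means and spreads
plot_sweep(sw)      # circles: storage, dots: loss, coloured by pattern
autoplot(micro)     # the synthetic histology itself
```

A thin command-line wrapper lives in `inst/cli/lobule-homog.R`
(`generate`, `homogenize`, `sweep`, `convergence` subcommands).

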