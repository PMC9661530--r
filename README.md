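# dphoresis

Measuring protein diffusiophoresis in a dead-end microfluidic channel.

A dead-end side channel is primed with a high-salt buffer and the main
channel is then flushed with a low-salt protein solution, creating a strong,
transient salt gradient at the dead-end inlet. A protein with
diffusiophoretic mobility Γ_p drifts in that gradient with velocity

    u_p = Γ_p ∇ln C

so proteins whose charge sign matches the more diffusive salt ion are pulled
into the dead-end and focused into a concentration peak; the opposite sign
is held out of the channel. The peak's position encodes Γ_p and its width
encodes the protein diffusion coefficient D_p, which makes the peak
fittable: one label-free fluorescence video of the dead-end yields D_p, Γ_p
and, through the electrophoretic coupling, the hydrodynamic radius and the
effective charge of the protein.

The package is aimed at microfluidics and protein-biophysics groups who want
to model such experiments, validate an analysis pipeline against synthetic
data, or fit measured intensity profiles.

## The model

In the similarity coordinate η = x/√(4 D_s t) (distance over the salt
diffusion length, with D_s = 2D₊D₋/(D₊+D₋) the ambipolar salt diffusivity)
the semi-infinite salt field is

    C/C₀ = α + (1 − α) erf(η),        α = C_main/C₀,

and the relative protein concentration N(η) solves the boundary-value
problem

    d/dη [ (D_p/D_s) N′ − (Γ_p/D_s) N dlnC/dη ] + 2η N′ = 0,
    N(0) = 1,  N(∞) = 0.

The drift competes with diffusion; for an attractive sign of Γ_p the
solution develops an interior maximum several-fold above the main-channel
concentration. The salt sets the strength of the spontaneous electric field
through β = (D₊−D₋)/(D₊+D₋); assuming electrophoresis dominates
diffusiophoresis, Γ_p = μ_p β k_BT/(Z e), which lets the fitted Γ_p be
converted to an electrophoretic mobility and — with the Einstein and
Stokes–Einstein relations — to an effective charge and hydrodynamic radius.

Modules:

* **physchem** — salt descriptors (β, ambipolar D_s) and the
  mobility/charge/radius conversions.
* **transport** — the similarity boundary-value model, peak statistics and
  parameter sweeps (`solve_similarity()`, `peak_stats()`,
  `sweep_effect_strength()`).
* **pdesim** — a finite-volume simulator of the coupled salt/protein
  transport in the finite channel (`simulate_channel()`), the independent
  oracle for the similarity model.
* **imaging** — synthetic fluorescence stacks (`synthesize_stack()`) and the
  analysis pipeline: illumination flattening, Scharr channel detection,
  width-averaged profile extraction, repeated Savitzky–Golay smoothing,
  main-channel normalization (`analyze_stack()`).
* **fitting** — frame selection, inlet-to-peak masking, peak-normalized
  nonlinear least squares over (D_p, Γ_p) and derived protein properties
  with uncertainties (`fit_profiles()`, `derive_properties()`).
* **pipeline/CLI** — YAML-configured end-to-end runs (`run_pipeline()`,
  `inst/scripts/dphoresis.R`).

## Worked example

```r
library(dphoresis)

licl <- builtin_salts("LiCl")
licl
#> <salt> LiCl: D+ = 1.03e-08 m^2/s, D- = 2.03e-08 m^2/s, Z = 1
#>   C0 = 200 mol/m^3 (dead-end), C_main = 2 mol/m^3, beta = -0.327

prof <- solve_similarity(similarity_params(
  dp_ratio    = 5.9e-11 / salt_diffusivity(licl),
  gamma_ratio = 1.5e-10 / salt_diffusivity(licl),  # attractive drift
  alpha       = 0.01))
prof
#> <similarity_profile> 2001 nodes on [0, 6]
#>   D_p/D_s = 0.004317, Gamma_p/D_s = 0.01098, alpha = 0.01
#>   peak: N = 4.494 at eta = 0.0480 (FWHM 0.0815)
```

A BSA-like protein (D_p = 5.9e-11 m²/s, attractive Γ_p = 1.5e-10 m²/s) is
focused 4.5-fold above its main-channel concentration, close to the inlet
(η ≈ 0.05). The full synthetic experiment — simulate, render a fluorescence
stack, analyze it and refit the protein parameters — runs from a shipped
configuration:

```r
res <- run_pipeline(system.file("extdata", "demo_config.yaml",
                                package = "dphoresis"), mode = "all")
res$fit
#> <fit_result>
#>   D_p     = 5.899e-11 +/- 2.5e-14 m^2/s
#>   Gamma_p = 1.507e-10 +/- 2.6e-14 m^2/s (attractive-positive)
#>   10 frames, 4820 points, rms residual 0.000846
#> <protein_properties>
#>   D_p     = 5.899e-11 m^2/s
#>   Gamma_p = 1.507e-10 m^2/s
#>   mu_p    = -1.796e-08 m^2/(V s)
#>   R_h     = 3.7 nm
#>   q_p     = -7.82 e
```

The configured truth (5.9e-11, 1.5e-10) is recovered to better than 1%; the
derived radius is the Stokes–Einstein radius of the fitted D_p and the
charge follows from the electrophoresis-dominated coupling through LiCl's
β = −0.327.

The same stages are available from a shell:

```sh
Rscript inst/scripts/dphoresis.R demo --out demo_out --seed 2
```

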