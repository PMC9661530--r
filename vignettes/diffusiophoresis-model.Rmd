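---
title: "Modelling and fitting protein diffusiophoresis in a dead-end channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and fitting protein diffusiophoresis in a dead-end channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dphoresis)
```

## The physical picture

A dead-end channel (50 × 50 × 500 µm³ in the reference device) is primed
with a salt solution at concentration $C_0$; at $t = 0$ a low-salt protein
solution starts flowing through the main channel past the inlet. Salt
diffuses out of the dead-end, protein diffuses in, and the salt gradient
drives a diffusiophoretic drift $u_p = \Gamma_p \nabla \ln C$. Because the
drift depends on $\nabla \ln C$, having the *high* salt in the dead-end
places both the steepest gradient and the smallest $C$ at the inlet, which
maximizes the effect.

For a binary symmetric electrolyte the two ions diffuse at different rates,
and a spontaneous (ambipolar) electric field arises to keep them together:

$$E \propto \beta\,\frac{k_B T}{Z e}\,\nabla \ln C, \qquad
  \beta = \frac{D_+ - D_-}{D_+ + D_-}.$$

For proteins the chemiophoretic (double-layer pressure) contribution is
subdominant, so the package models diffusiophoresis as purely
electrophoretic:

$$\Gamma_p = \mu_p\,\beta\,\frac{k_B T}{Z e},$$

with $\mu_p$ the electrophoretic mobility. This is also the model's main
limitation: chemiophoresis and any salt-concentration dependence of the
$\zeta$-potential are ignored, which biases the inferred *charge* but not
the inferred *size* (the size comes from $D_p$ alone through
Stokes–Einstein).

Sign convention: throughout the package $\Gamma_p > 0$ means drift *up* the
salt gradient, into the dead-end (the attractive, peak-forming case). Some
reports quote the attractive case with a negative sign, depending on the
orientation of the coordinate axis; `fit_config()` keeps the
attractive-positive convention explicit rather than guessing.

## The similarity model

With the salt diffusing as a semi-infinite field with the ambipolar
coefficient $D_s = 2 D_+ D_- /(D_+ + D_-)$, everything collapses in the
similarity coordinate $\eta = x/\sqrt{4 D_s t}$:

$$\frac{C}{C_0} = \alpha + (1 - \alpha)\,\mathrm{erf}(\eta), \qquad
  \alpha = C_{\mathrm{main}}/C_0,$$

and the relative protein concentration $N(\eta)$ obeys

$$\frac{d}{d\eta}\!\left[\frac{D_p}{D_s} N' -
  \frac{\Gamma_p}{D_s}\,N\,\frac{d\ln C}{d\eta}\right] + 2\eta N' = 0,
  \qquad N(0) = 1,\; N(\infty) = 0.$$

The $2\eta N'$ term is tied to this definition of $\eta$ (the factor 4
under the square root); both must be kept consistent. With $\Gamma_p = 0$
the solution is the closed form $1 - \mathrm{erf}(\eta\sqrt{D_s/D_p})$,
which the test suite uses as an oracle.

### Numerical treatment

The equation is linear in $N$, so `solve_similarity()` discretizes it with
three-point finite differences and solves one sparse tridiagonal system —
no iteration, no initial guess. Choices that matter:

* **Mesh.** Geometric mesh on $[0, \eta_{\max}]$ with growth ratio 1.005
  (capped at 1.02), 2001 nodes by default: the drift field
  $d\ln C/d\eta$ is steepest at the inlet ($\approx 112$ at
  $\alpha = 0.01$), so resolution is concentrated there.
* **Hybrid differencing.** The advective term uses central differences
  where the cell Péclet number $|v|h/(D_p/D_s) \le 2$ and first-order
  upwinding beyond, keeping the matrix stable without smearing the peak
  (the large-Péclet region carries $N \approx 0$).
* **Truncation.** $\eta_{\max} = 6$ with a Dirichlet zero stands in for the
  semi-infinite far field; doubling $\eta_{\max}$ changes the solution on
  $[0,4]$ by $<10^{-13}$ at matched resolution.
* **$\alpha$ floor.** $d\ln C/d\eta \to \infty$ as $\alpha \to 0$, so a
  nominally salt-free main channel is floored at $\alpha = 10^{-4}$
  (configurable).
* **Residual and positivity checks.** The solve fails loudly if the
  relative residual exceeds $10^{-10}$ or the solution dips below
  $-10^{-6}$; values in $(-10^{-6}, 0)$ are clipped to zero.

For the reference attractive case (LiCl with printed diffusivities,
$D_p = 5.9\times10^{-11}$, $\Gamma_p = +1.5\times10^{-10}$ m²/s,
$\alpha = 0.01$) the model predicts a 4.49-fold concentration peak. An
independent collocation solver reproduces this value to five digits.

## The finite-volume oracle

`simulate_channel()` integrates the coupled fields on the finite channel:
salt by pure diffusion with $D_s$, protein with flux
$J = -D_p \partial_x N + \Gamma_p N \partial_x \ln C$. The inlet cell face
is Dirichlet (main-channel values), the closed end is no-flux, matching the
boundary conditions of the experiment; time zero is the flow switch. The
protein flux uses Scharfetter–Gummel exponential fitting — exact for
piecewise-constant drift, reducing to central differencing at small Péclet
and to upwinding at large — and `deSolve::ode.1D` does the stiff time
integration with a banded Jacobian. $\ln C$ is evaluated on concentrations
floored at `alpha_floor * c_reservoir`.

The simulator is deliberately a *different* discretization of *different*
equations (finite channel, real time) from the similarity BVP, which makes
the two usable as mutual oracles: mapped into $\eta$ while the salt front
is far from the closed end, simulated profiles land on the BVP curve within
2% and collapse onto each other across times within 2%. Once the front
reaches the channel end the collapse visibly fails — the semi-infinite
assumption is broken, which is exactly why late frames are excluded from
fits. Because the scheme's startup (a step initial condition whose peak is
initially thinner than any fixed grid) converges at first order, the 2%
oracle agreement is demonstrated on a 2 mm channel with 3200 cells at
$t \ge 8$ s; production synthetic data instead use `similarity_states()`,
which evaluates the similarity solution exactly on the channel grid.

What the 1D model deliberately omits: the main channel is treated as a
perfect reservoir. In the real device protein is locally depleted at the
inlet, which *reduces* observed peak heights relative to the 1D
prediction; the package asserts only the direction of that effect
(simulated peak ≤ similarity peak) and absorbs the height mismatch by
fitting peak-normalized shapes.

## The synthetic microscope

`synthesize_stack()` emulates a label-free UV autofluorescence microscope:

* frame value $I = B(x,y)\,[b + s\,N\,e^{-\lambda (k-1)}] + \varepsilon$,
  with $B$ a second-order polynomial illumination surface, $b$ an ambient
  fluorescence baseline (default 0.08), $s$ the per-concentration signal
  (default 0.4), $\lambda$ a per-frame photobleaching decay and
  $\varepsilon$ Gaussian read noise;
* the dead-end occupies a 50-px-wide horizontal band (1 µm/px) and the
  perpendicular main channel a full-height band left of the inlet;
* frames are taken at log-spaced times, the experimental tactic that limits
  the number of exposures and hence bleaching.

Defaults represent the study conditions: 10 frames log-spaced over
0.5–8 s — the window in which the salt gradient persists in a 500 µm
channel at the printed diffusivities — SNR 10
(`noise_sigma = signal/10`) and a bleach rate of 0.004/frame for "noisy"
runs. What the generator does **not** emulate: channel rotation or tilt
(axis-aligned only), inlet depletion, adsorption, shot-noise statistics,
bleaching inhomogeneity. Passing tests therefore demonstrate correctness
of the pipeline's *algorithms*, not robustness to every artifact of real
microscopy.

## The image-analysis pipeline

`analyze_stack()` chains the stages, each individually exported:

1. **Detection** (`detect_channel()`): Scharr derivative kernels; the wall
   response is averaged *signed* along the channel so incoherent noise
   cancels, and the two strongest responses (sub-pixel, by parabolic
   interpolation) bound the channel. The inlet is found the same way from
   the rows *outside* the channel band — inside it, the protein peak
   itself would bias the edge. Detection of the inlet to ~1 px matters
   because the peak sits only tens of µm from it.
2. **Flattening** (`flatten()`): a 6-coefficient 2D quadratic is fitted to
   the pixels outside the channel band (and right of the inlet) and the
   frame is divided by it — division, because the illumination bias is
   multiplicative and the later normalization is also ratio-based; a
   subtraction mode exists for dark-current-dominated regimes. If the
   protein fluorescence (gauged on the main-channel strip) exceeds 10× the
   outside background, the background cannot be estimated and the frame is
   used as-is, flagged in metadata rather than raised as an error.
3. **Extraction** (`extract_profile()`): mean over the central 60% of the
   detected width (wall rows excluded), ambient background level
   subtracted, so the profile is proportional to concentration.
4. **Smoothing** (`smooth_profile()`): Savitzky–Golay, window 11 px, order
   3, 3 passes. The repeated filter suppresses noise variance ≥5× while
   moving a peak by less than a grid step; it is also the pipeline's main
   resolution limit for very early, very narrow peaks.
5. **Normalization** (`normalize_stack()`): division by the median
   main-channel reference of the last five frames — late frames avoid the
   initial flow transient, the median tolerates one outlier frame. The
   reference region is the in-channel strip left of the inlet
   (configurable).

On noise-free stacks the unsmoothed chain reproduces the simulated field to
machine precision; with SNR 10, planted quadratic illumination and
bleaching, profiles stay within 5% of truth.

## Fitting

Following the measurement protocol: only frames showing a concentration
peak are fitted; frames with mean fluorescence in the last fifth of the
channel above 10% of the peak are dropped (semi-infinite assumption
broken; the 10% quantification is this package's choice, logged in the
result). The data between inlet and peak are masked — there the measured
profiles sit systematically above the 1D model because the main channel is
not a perfect reservoir — and both data and model are normalized by their
peak height, which absorbs the 1D/2D peak-height discrepancy. Fitting
peak-normalized rather than absolute profiles is a deliberate choice;
`fit_config(normalize = "absolute")` keeps the alternative.

The optimizer is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) over
$(\log_{10} D_p, \log_{10} \Gamma_p)$ — log-parametrization because the
plausible ranges span decades — with three seeded starts to guard against
the shallow $D_p$–$\Gamma_p$ trade-off; ties go to the smaller
$|\Gamma_p|$. $\alpha$ is fixed from the salt concentrations by default and
can be freed within $[10^{-4}, 1]$. Uncertainties come from the
Jacobian-based covariance at the optimum scaled by the residual variance,
delta-method-transformed to linear scale.

`derive_properties()` then applies the forward relations in reverse:
$R_h = k_BT/(6\pi\eta D_p)$, $\mu_p = \Gamma_p Z e/(\beta k_B T)$,
$q_p = \mu_p k_B T/D_p$, with first-order error propagation using the fit
covariance. A salt with $\beta = 0$ carries no mobility information and
raises an error. Note the leverage of small $\beta$: at fixed $\Gamma_p$,
the inferred $|q_p|$ under KCl ($\beta = -0.019$) is ~17× that under LiCl
($\beta = -0.327$) — weak-β salts amplify charge uncertainty.

Under the default study conditions (20 stacks at SNR 10, seeds 0–19), the
median relative recovery error of both $D_p$ and $\Gamma_p$ is below 1.5%
with no sign errors; the acceptance suite asserts the much looser 15%
bound to leave room for less favorable optics.

## Parameter reference

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `d_plus`, `d_minus` | LiCl: 1.03e-8 / 2.03e-8 | m²/s | printed ionic diffusivities; only ratios enter the dimensionless model |
| `c_reservoir`, `c_main` | 200 / 2 | mol/m³ | dead-end priming and main-channel salt (α = 0.01) |
| `temperature`, `viscosity` | 298 / 1e-3 | K / Pa·s | solvent conditions for kT and Stokes–Einstein |
| `eta_max`, `n_grid` | 6 / 2001 | – | BVP truncation and mesh |
| `alpha_floor` | 1e-4 | – | drift singularity guard |
| `n_cells` | 400 | – | finite-volume cells (3200 for the oracle-equivalence check) |
| `pixel_size` | 1e-6 | m/px | 500 px across the 500 µm channel |
| `window`, `order`, `passes` | 11 / 3 / 3 | – | Savitzky–Golay settings |
| `center_fraction` | 0.6 | – | channel width fraction averaged |
| `tail_fraction`, `tail_threshold` | 0.2 / 0.1 | – | frame-rejection rule |
| `n_starts` | 3 | – | multistart count |

The printed LiCl ionic diffusivities are roughly tenfold above handbook
scales; they are used verbatim because β and every dimensionless ratio of
the salt model are invariant under a common rescaling. One consequence is
that, mixing them with a realistic protein $D_p$, the similarity-regime
window of the 500 µm channel sits at sub-second to few-second times, which
is why the default frame times are 0.5–8 s; the dimensionless physics is
unchanged.

## Known limitations

* Chemiophoresis and ζ(C) dependence are outside the model: derived
  charges are effective, assumption-bound values.
* The finite-volume startup is first-order accurate while the peak is
  thinner than a cell, so very early simulated frames under-resolve the
  peak height.
* The image pipeline assumes an axis-aligned channel and multiplicative
  illumination bias.
* Bleaching is mitigated (log-spacing, late-frame normalization), not
  corrected: with the default 0.004/frame rate the residual bias is ≤3%.
* Fits on real data inherit the 1D reservoir assumption through the
  inlet-to-peak mask and peak normalization; absolute concentrations are
  not recovered.
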