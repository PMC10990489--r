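---
title: "Quantifying FGFR1 ligand bias: models, measurement choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FGFR1 ligand bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgfbias)
```

# The problem

FGFR1 is activated by several FGF ligands that co-occur during limb
development. Two ligands can differ in *potency* (EC~50~, the
concentration giving half the maximal response) and *efficacy* (E~top~,
the plateau response), but they can also differ *qualitatively*: one
ligand may preferentially drive one downstream response over another.
That qualitative difference — ligand bias — is invisible in any single
dose-response curve and only appears when at least two responses and two
ligands are compared on a common scale. `fgfbias` implements the complete
chain needed for such a comparison: oligomer-state analysis of the
receptor itself (brightness imaging), globally scaled dose-response
fitting of downstream readouts, bias-coefficient calculation with
uncertainties, and intrinsic-FRET analysis of receptor dimer geometry.

# Molecular brightness and the Z comparison

For mobile fluorophore-tagged receptors imaged with a photon-counting
detector, the brightness of a small membrane region,

$$\varepsilon = \frac{\sigma^2}{\langle I \rangle} - 1,$$

is proportional to the average oligomer size: a dimer is twice as bright
as a monomer at equal receptor density. `segment_membrane()` tiles the
image into non-overlapping square regions (default 15 × 15 pixels,
top-left origin, partial border tiles dropped; an optional mask restricts
tiles to the membrane), and `molecular_brightness()` evaluates ε per
region with the population variance. Brightness distributions pooled over
many cells are close to log-normal, so `fit_log_gaussian()` histograms
log~10~ ε and fits the three-parameter Gaussian
$a\,e^{-(\theta-m)^2/2s^2}$ to the max-1-normalized counts.

Two conditions are compared with
$Z = |m_1 - m_2| / \sqrt{q_1^2 + q_2^2}$ where $q = s/\sqrt{n_\mathrm{cells}}$,
and $Z > 2$ is read as "different". Two points matter here:

* $n_\mathrm{cells}$ is supplied as metadata — the replication unit is
  the cell, not the region of interest, so $q$ is deliberately much
  larger than the fit error of $m$. This makes the Z test conservative
  (matched populations essentially never exceed Z = 2) while leaving the
  monomer/dimer separation, which is ~log~10~2 ≈ 0.3 in $m$, enormous on
  the q scale.
* ε ≤ 0 values cannot be log-transformed. They are discarded before
  histogramming and the discarded fraction is reported on the fit object
  (`frac_discarded`). With the defaults used here the fraction is
  negligible; a large fraction signals a background-dominated sample.

Log base 10 is used throughout (both for brightness and for the bias
coefficients), and the histogram bin width defaults to Freedman–Diaconis
on the log values; both are overridable.

## Numerical choices in the histogram fit

The Gaussian is fitted by Levenberg–Marquardt (`minpack.lm::nlsLM`,
up to 1000 iterations — every fit in this package converges in far
fewer). Only occupied bins enter the fit; empty bins carry no counts and
no variance estimate, and excluding them makes the fit exactly invariant
to multiplying all counts by a constant (the max-1 normalization then
guarantees identical input). Bins are weighted by the inverse of their
count, the Poisson variance of a histogram bin. We verified by simulation
(200 seeded log-normal samples per condition) that unweighted least
squares yields standard errors for $m$ that are optimistic — ±2·se~m~
covered the generating mean in only ~85–87% of runs — while
Poisson-weighted fitting restores ~90–93% coverage without changing the
$(m, s)$ estimates. `weighting = "none"` remains available.

Receptor surface density (`estimate_density()`) is the
background-subtracted mean count divided by (counts per fluorophore ×
pixel area); the calibration is an input, not something the package
estimates.

# Dose-response scaling and fitting

Band intensities from western blots arrive as numbers (one gel = one
dose-response curve). The scaling protocol is:

1. `scale_within_gel()` — divide each gel's curve by its own maximum.
2. `average_replicates()` — average across gels per concentration (mean,
   SEM, n) and re-normalize so the maximum mean is 1; SEMs are scaled by
   the same factor. Concentration grids are merged across gels only
   within a 1% relative tolerance; anything larger is an error.
3. `glue_scale()` — the *gluing gel* re-runs each ligand's maximal
   sample on one common gel; per-ligand coefficients are the glue means
   divided by the largest glue mean, so the full agonist keeps max 1 and
   partial agonists are scaled down.

For loss-type readouts (receptor downregulation, collagen type 2), the
zero-ligand band is the largest: `loss_transform()` sets the baseline to
1 and returns 1 − scaled value, so loss is 0 at zero ligand.

Curves that decline at high dose (the FGF4 phenotype) cannot be described
by a rectangular hyperbola; `truncate_for_fit()` keeps the prefix of the
grid up to the highest concentration whose response is within 10% of the
maximum — the 10% reading is relative (y ≥ 0.9·max y), consistent with
the 5–10% error level typical of blot quantification.

`fit_hill()` fits $y = x\,E_\mathrm{top}/(x + \mathrm{EC}_{50})$ (Hill
coefficient fixed at 1) by Levenberg–Marquardt with weights 1/SEM²,
initialized at E~top~ = max(y) and EC~50~ = the concentration nearest
half-max, with positivity bounds. Zero-concentration points are retained:
the model passes through the origin, so a baseline-subtracted zero-dose
response carries information.

## The measurement model behind the fit uncertainties

Two choices here were made after explicit calibration simulations, and
they matter for every downstream uncertainty:

* **Pooled relative error.** With ~3 replicate gels a per-point SEM is
  estimated with 2 degrees of freedom; inverting such a noisy quantity
  into a weight destroys the fit's frequentist calibration (±2SE coverage
  ~70% in simulation, driven by points whose SEM is small by chance).
  Blot errors scale with band intensity, so the pipeline wrapper
  (`fit_dose_response()`) pools the per-point SEMs into a single
  coefficient of variation per curve and weights by (CV·y)⁻². The
  low-level `fit_hill()` default keeps the raw SEMs so that all-equal
  SEMs reduce exactly to the unweighted fit.
* **Known-error covariance.** When weights are supplied they are treated
  as known measurement variances: parameter standard errors come from the
  weighted-fit covariance *without* the estimated residual-scale factor.
  Rescaling by the reduced chi-square (the `nls` summary default)
  re-introduces a noisy factor estimated on ~6 degrees of freedom and
  degraded coverage to ~84% even with exact weights.
* **Global-scale uncertainty.** Multiplying a whole curve by an uncertain
  gluing-gel coefficient shifts E~top~ coherently — invisible to the
  point-wise covariance — so `glue_scale()` records each coefficient's
  relative SE and `fit_dose_response()` adds it in quadrature to the
  E~top~ standard error (EC~50~ is unaffected by a pure scale).

With these choices, 200 seeded triplicate experiments per ligand (7-point
log grid plus zero, 7% multiplicative noise, hidden log-normal gel
scales) put the generating E~top~ and EC~50~ inside ±2SE in ~96% of
fits, through the *entire* scaling chain.

# Bias coefficients

For two responses (numerator/denominator) and one ligand,

$$\beta' = \log_{10}\!\left[\frac{(E_\mathrm{top}/\mathrm{EC}_{50})_\mathrm{num}}
{(E_\mathrm{top}/\mathrm{EC}_{50})_\mathrm{den}}\right],
\qquad \beta = \beta'_\mathrm{ligand} - \beta'_\mathrm{reference},$$

with FGF8 as the reference. β is invariant to any per-response
multiplicative rescaling applied across all ligands (units cancel),
antisymmetric under swapping the responses, and transitive in the
reference — all verified as properties in the test suite.

**Sign convention.** The conventional row labels ("response A vs
response B") do not determine the sign. The API therefore always takes
explicit numerator/denominator responses and never infers order from
labels; the bundled map (`fgfr1_bias_map()`) pins numerator = the
second-listed response for the phosphorylation and downregulation rows
and numerator = collagen loss for the chondrocyte row, which reproduces
the published signs consistently.

**Error propagation** (`propagate_error()`) supports four methods:
*functional* (one-sided positive perturbation, the default, following the
standard textbook convention for multi-variable functions),
*symmetric* (centred perturbations), *derivative* (first-order
numerical partials) and *montecarlo* (independent normal draws, seeded).
For β all eight fit parameters are perturbed in a single propagation.
Method sensitivity is real for the log of a ratio whenever a relative
error approaches ~50%, and the acceptance test prints all four methods
side by side rather than picking one silently.

One published SE is not reproducible under any method: for the FGF9
collagen-loss/growth-arrest coefficient the published ±0.18 is smaller
than what the published EC~50~ uncertainty (51% relative) alone implies
(≥0.18 from that single term; ≥0.22 in quadrature with the remaining
seven). The package reports the faithful propagation (0.24 functional)
and we flag the printed value as internally inconsistent.

**Significance.** `anova_summary()` reconstructs one-way ANOVA from
(mean, SEM, n) summaries — SS~between~ from the means, SS~within~ =
Σ sem²·n·(n−1) — matching raw-data ANOVA exactly when the summaries are
exact. `compare_linear_slopes()` handles near-linear readouts (viability,
caspase activity) with a pooled-variance t-test on the OLS slope
difference.

# QI-FRET and dimer geometry

For constitutive dimers — FRET independent of expression level, checked
explicitly by `check_concentration_independence()` via the regression of
E on total receptor concentration — the measured efficiency in a vesicle
relates to the intrinsic FRET of the dimer by $E = \tilde{E}\,x_A$, with
$x_A$ the acceptor fraction. `intrinsic_fret()` excludes vesicles with
$x_A \le 0.1$ (default): dividing by a tiny acceptor fraction amplifies
measurement noise without bound, and excluded records are counted and
reported rather than silently dropped. Per-vesicle Ẽ values outside
[0, 1] are retained for histogramming — they are noise, not errors — but
a mean outside (0, 1) cannot be converted to a distance.

The separation between the fluorophores follows from the Förster
relation under free rotation,
$d = R_0 \left[(1-\tilde{E})/\tilde{E}\right]^{1/6}$, with R₀ = 53.1 Å
for eYFP/mCherry by default. The distance SE is propagated from the
Gaussian mean's SE with the same functional method as the bias module.

R₀ is exposed as a parameter deliberately: published distances of
55/56/60 ± 1 Å for this system are not reproducible from the published
intrinsic-FRET values (0.54/0.52/0.42) with R₀ = 53.1 Å — they imply an
effective R₀ near 57 Å. The package computes the relation faithfully and
leaves the choice of R₀ to the user; no distance value is asserted
against published numbers.

# What the synthetic generators emulate — and what they do not

* `simulate_fif_image()` places oligomers uniformly at random and draws
  per-pixel Poisson counts with rate = counts-per-fluorophore × local
  fluorophore number + background. Defaults (60 px field, 150
  receptors/µm², 0.0256 µm² pixels, 5 counts/fluorophore) sit in the
  measured 100–200/µm² density range and give monomer ε ≈ 5, dimer
  ε ≈ 10. The expected *fluorophore* density is held fixed across
  oligomer mixes, so brightness ratios across conditions are at equal
  receptor density. There is no point-spread function, no membrane
  topography, no detector afterpulsing: real images share the Poisson
  statistics but not the spatial correlations, so passing tests validate
  the estimator chain, not microscope physics.
* `simulate_dose_response()` draws band intensity = gel scale ×
  Hill(x) × (1 + N(0, σ)) with σ = 0.07 by default (the 5–10% blot error
  range), log-normal hidden gel scales (sdlog 0.3, a realistic 2-fold
  spread), and a 3-sample gluing gel per ligand. The biphasic FGF4-like
  decline is a phenomenological multiplicative factor
  $1/(1 + s(x/x_d - 1))$ above a threshold $x_d$ — it exists to exercise
  the truncation rule, not to model the oligomerization mechanism behind
  the real decline.
* `simulate_vesicles()` draws donor/acceptor concentrations log-uniformly
  (default 50–2000, spanning the >3-fold range the constitutive check
  requires) and E = Ẽ·x_A + N(0, 0.05); an optional linear
  concentration term mimics a monomer-dimer equilibrium for negative
  controls. Real vesicle data additionally carry segmentation and
  calibration errors that are not modeled.

All generators take an explicit seed and restore the caller's RNG state;
identical (spec, seed) pairs give identical output.

# Problem sizes used by the test suite

The calibration properties are established at sizes chosen to make the
statistical assertions meaningful while staying desk-scale: 200 simulated
triplicate-gel experiments for dose-response coverage, 100 simulated
cells per condition and 20 repetitions for the monomer/dimer Z
discrimination (with 30–40 cells in the faster unit-level checks), 300
vesicles for FRET recovery, and 100 end-to-end runs for bias-coefficient
coverage. These are the package's reference conditions; larger runs only
tighten the same estimates.

# Known limitations

* Brightness is mapped to oligomer size only through proportionality; no
  absolute oligomer-size calibration is attempted.
* The Hill coefficient is fixed at 1; variable-slope or genuinely
  biphasic models are out of scope (declining curves are truncated, and
  the fitted parameters then describe the ascending, dimer-dominated
  regime).
* ANOVA from summary statistics assumes equal-variance groups (no Welch
  correction), matching standard one-way ANOVA on summaries.
* Kinetic time courses are supported only as max-normalized traces via
  `scale_within_gel()`; no kinetic model is fitted.
* The two printed-value inconsistencies noted above (effective R₀; one
  propagated SE) are documented rather than matched.
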