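# fgfbias

Quantitative detection of **ligand bias** (biased agonism) at fibroblast
growth factor receptor 1 (FGFR1), for receptor-pharmacology and
quantitative-imaging labs. Different FGF ligands (FGF4, FGF8, FGF9) can
activate the same receptor yet preferentially engage different downstream
responses; this package implements the full analysis chain needed to
demonstrate and quantify that, from raw measurements to bias coefficients
with uncertainties:

1. **FIF spectrometry** — molecular brightness of membrane receptors from
   photon-counting confocal images. Each 15×15-pixel region of interest
   yields ε = σ²/⟨I⟩ − 1, proportional to the average oligomer size;
   log₁₀-brightness histograms are fitted with Gaussians and conditions
   compared with Z = |m₁ − m₂| / √(q₁² + q₂²), q = s/√n_cells.
2. **Dose-response analysis** — replicate western-blot band intensities
   are scaled within each gel (max = 1), averaged, and placed on one
   global scale with a *gluing gel*; declining (biphasic) curves are
   truncated at the highest concentration within 10% of the maximum; the
   rectangular hyperbola *y = x·E_top/(x + EC₅₀)* (Hill n = 1) is fitted
   by weighted Levenberg–Marquardt least squares.
3. **Bias coefficients** — per-ligand transduction coefficients
   β′ = log₁₀[(E_top/EC₅₀)_num / (E_top/EC₅₀)_den] and pairwise bias
   β = β′(ligand) − β′(reference FGF8), a ΔΔlog₁₀ that cancels units and
   assay scales. Standard errors are propagated by the functional,
   derivative, symmetric or Monte Carlo method; significance comes from
   one-way ANOVA reconstructed from (mean, SEM, n) summaries, and linear
   readouts are compared by a pooled-variance slope t-test.
4. **QI-FRET** — per-vesicle intrinsic FRET Ẽ = E/x_A for constitutive
   dimers (x_A the acceptor fraction), Gaussian histogram summaries, and
   fluorophore separation d = R₀·((1 − Ẽ)/Ẽ)^(1/6) with R₀ = 53.1 Å for
   eYFP/mCherry.
5. **Synthetic data** — seeded generators for photon-counting membrane
   images, replicate gel tables with hidden per-gel scales, and vesicle
   records, so the whole chain is testable without any raw data.

## Worked example

Recompute the bias map from the bundled published dose-response fit
parameters (`fgfr1_fit_parameters()`):

```r
library(fgfbias)
b <- reproduce_bias_map()
b[b$label %in% c("pY653/654 vs pFRS2", "collagen2_loss vs growth_arrest"),
  c("ligand", "response_num", "response_den", "beta", "se")]
#>  ligand   response_num  response_den   beta    se
#>    FGF4          pFRS2     pY653/654 -0.614 0.149
#>    FGF9          pFRS2     pY653/654 -0.780 0.137
#>    FGF4 collagen2_loss growth_arrest -1.771 0.167
#>    FGF9 collagen2_loss growth_arrest -1.130 0.237
```

β < 0 with numerator FRS2 phosphorylation means FGF4 and FGF9 engage FRS2
*less*, relative to receptor autophosphorylation, than the reference
ligand FGF8 does — equivalently, FGF8 is biased toward FRS2. The
magnitudes (−0.61, −0.78 in log₁₀ units, i.e. 4–6-fold) are recovered
exactly from the (E_top, EC₅₀) pairs; the `se` column is the functional
error propagation through all eight fit parameters.

Brightness-based oligomer-state comparison on synthetic images:

```r
mono <- simulate_fif_condition(fif_sim_spec(oligomer_sizes = c("1" = 1)),
                               n_cells = 100, seed = 2)
dimr <- simulate_fif_condition(fif_sim_spec(oligomer_sizes = c("2" = 1)),
                               n_cells = 100, seed = 3)
z <- z_statistic(fit_log_gaussian(mono), fit_log_gaussian(dimr))
#> log-brightness means 0.695 vs 0.994, Z = 46.0 -> different
```

The dimer population is twice as bright (0.994 − 0.695 ≈ log₁₀ 2) and the
Z-statistic far exceeds the Z = 2 decision threshold.

QI-FRET on synthetic vesicles generated with intrinsic FRET 0.42:

```r
rec <- simulate_vesicles(fret_sim_spec(n_vesicles = 300, e_tilde = 0.42),
                         seed = 1)
summarize_fret(rec, r0 = 53.1)
#> intrinsic FRET 0.427 +/- 0.009, distance 55.8 +/- 0.3 A (n = 278)
```

A pipeline driver (`run_pipeline()`, with a thin `inst/cli/fgfbias`
wrapper) ties the stages together from a YAML/JSON config and writes all
intermediate CSVs plus a JSON summary and run log.

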