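# chladapt

Condition-aware, domain-adaptive retrieval of leaf chlorophyll content
(µg·cm⁻²) from canopy reflectance spectra measured under discrete shading
levels.

## The problem

Inversion models for leaf chlorophyll are conveniently trained on a
simulated source domain — a lookup table of (spectrum, chlorophyll) pairs
from a forward model — and applied to field spectra. Shading breaks this
transfer twice over: each shading level S1 (full sun) … S4 (heavy shade)
changes the *distribution* of the measured spectra (brightness, diffuse
light, noise) **and** the *mapping* from spectrum to chlorophyll (the
spectral sensitivity to chlorophyll itself depends on the illumination
regime). This conditional domain shift is what `chladapt` addresses: the
shading level is treated as an explicit conditioning variable in the
representation, in the alignment loss, and in the training objective.

The package is for researchers in hyperspectral plant phenotyping who
want a fully reproducible, synthetic-data-backed implementation of this
workflow: preprocessing, diagnostics, feature selection, source-domain
simulation, the model family, and the evaluation protocol.

## What is inside

* **Spectral core** — `spectral_dataset` on a 1-nm 400–900 nm grid;
  crop, Savitzky–Golay smoothing, continuum removal (upper convex hull),
  standard normal variate, first derivative; region slicing (green peak
  500–600 nm, red edge 680–760 nm); lossless wide/long CSV I/O.
* **Separability diagnostics** — band-wise Fisher discriminant ratio
  profiles (`band_fdr`) and PERMANOVA (`permanova`) with pseudo-F,
  permutation p (floor `1/(B+1)`, i.e. 0.001 at 999 permutations) and
  R²; `separability_table` crosses transforms with regions.
* **Feature selection** — Pearson screen then a Boruta shadow-feature
  wrapper over random forests, run per preprocessing branch and merged
  (`two_stage_select`).
* **Simulated source domain** — Latin-hypercube parameter sampling, a
  surrogate forward model with chlorophyll-dependent red absorption and
  red-edge position (any PROSAIL-style callable can be plugged in), LUT
  construction (`build_lut`), and the SPAD calibration
  `spad_to_chl(s) = 117.1·s/(148.84 − s)`.
* **Synthetic campaign** — `generate_campaign` renders a four-condition
  shaded field campaign with both marginal (illumination) and
  conditional (mapping) shifts.
* **Model family** — five ablation variants on one residual-MLP
  backbone (256-d features, dropout 0.2, batch 64): `ResDNN`, `GAI`
  (global CORAL), `CA` (target-conditioned CORAL), `CA-IE` (+ 32-d
  condition embedding), `CAI-DAI` (+ heteroscedastic head and learnable
  per-condition loss weights). Losses: `coral_loss`
  (‖Cs−Ct‖²_F/(4d²)), `tc_coral_loss`, `het_nll`,
  `condition_weighted_loss`. Forward, backward and Adam are implemented
  directly on matrices; all gradients are finite-difference-verified in
  the tests.
* **Protocol** — stratified plant-exclusive splits at ratios 3:7 … 7:3
  (`split_target`), 8:2 source pretraining with early stopping
  (`pretrain_source`), condition-stratified adaptation with a streaming
  source batch (`adapt`), metrics with per-condition MAE breakdown
  (`evaluate_model`), and the full variant × ratio grid (`ablate`).

A thin CLI lives at `inst/cli/chladapt`
(`simulate | campaign | preprocess | diagnose | select | evaluate | ablate`).

## Worked example

```r
library(chladapt)

camp <- generate_campaign(seed = 42, n_per_condition = 80)  # 320 plants, S1..S4
lut  <- build_lut(n = 5000, seed = 42)                      # simulated source

base <- run_variant(camp, lut, "ResDNN", ratio = "3:7", seed = 42,
                    pretrain_epochs = 40)
full <- run_variant(camp, lut, "CAI-DAI", ratio = "3:7", seed = 42,
                    selection = base$selection,   # shared feature set
                    pretrain_epochs = 40)
base$report
#> <evaluation_report> ResDNN: R2 = 0.806, nRMSE = 6.4%, MAE = 1.567 ug/cm2
#>   per-condition MAE: S1=1.105, S2=0.849, S3=1.782, S4=2.532 (mean 1.567, CV 0.481)
full$report
#> <evaluation_report> CAI-DAI: R2 = 0.863, nRMSE = 5.4%, MAE = 1.227 ug/cm2
#>   per-condition MAE: S1=0.659, S2=0.680, S3=1.229, S4=2.340 (mean 1.227, CV 0.642)
```

Read: with only 30% of the target plants labelled for fine-tuning, the
condition-blind baseline degrades toward heavy shade (S4 MAE
2.53 µg·cm⁻² vs ~1 in full sun) — the conditional mapping shift at
work. The full framework cuts overall MAE from 1.57 to 1.23 µg·cm⁻²,
with the largest gains in the lightly shaded conditions. R² is the
share of chlorophyll variance explained on held-out plants; nRMSE is
RMSE relative to the mean observed chlorophyll.

Diagnostics on the same campaign:

```r
br <- preprocess_branches(camp)
permanova(slice_region(br$SNV, spectral_region("red_edge")), n_perm = 999, seed = 11)
#> PERMANOVA: pseudo-F = 4.927, p_perm = 0.001, R2_perm = 0.045 (999 permutations)
```

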