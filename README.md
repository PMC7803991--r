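# molgcn

Quantitative structure–activity (QSAR) modelling with graph convolutional
neural networks, in R.

Early drug discovery needs *quantitative* activity predictions — a compound
with an IC50 of 1 nM and one of 1 µM are both "active" to a classifier, but
only one of them is a lead. `molgcn` is for computational chemists and
method developers who want a complete, reproducible pipeline that goes from
a raw ChEMBL-style activity table to an ensemble regressor of
pIC50 = −log10(activity in molar), plus the diagnostics to judge whether a
random train/test split quietly shifted the chemistry under the model.

The package implements:

* **Curation** — confidence/assay/unit/relation filters, salt stripping and
  neutralization, canonicalization, pIC50 transform (9 − log10 v[nM]), and
  most-active-wins duplicate aggregation, with full bookkeeping.
* **A graph convolutional regressor** — 75-bit binary atom features; per
  block h′ᵥ = maxpool ReLU(BN(Wₛᵀhᵥ + Wₙᵀ Σᵤ∈N(v) hᵤ + b)) over the closed
  neighborhood; atomwise dense layer; tanh-squashed sum-gather ("neural
  fingerprint"); single linear output. Trained with Adam on MSE in a fast
  RcppArmadillo core, stopped by a 100-epoch-block rule on validation MAE,
  with the final snapshot chosen by the validation score
  **2R2_MAE = (R² − MAE) + R²**.
* **Hyperparameter search** — Gaussian-process Bayesian optimization
  (Matérn 5/2, expected improvement) per architecture tier (1, 2, 3–4 conv
  layers), tiered retention rules (0.45 re-search trigger, 0.40 floor,
  deeper-must-beat-shallower), a reproducibility filter on fixed-seed
  retraining, and unweighted ensembling.
* **Scaffold-diversity diagnostics** — Murcko carbon skeletons, size-ordered
  10,000-per-bin scaffold binning, Shannon entropy H (bits), and the
  Kullback–Leibler divergence of each split subset against the unsplit
  dataset.
* **Virtual screening** — logP, predicted target/anti-target activity and
  prior-assay exclusion filters over a candidate library, with an audited,
  ranked hit table.
* **A synthetic-data generator** — ChEMBL-shaped tables from a scaffold/
  substituent grammar with a planted additive SAR, exact junk/duplicate/
  censoring quotas, and invertible ground truth, so the entire pipeline is
  testable end to end without any database download.

## A worked example

Simulate a 1000-row raw activity table with assay noise of 0.3 pIC50 units,
curate it, split 80:10:10, run a reduced search (10 trials × 2 repeats over
the 1- and 2-layer tiers), retrain the retained candidates under the block
rule, ensemble, and report:

```r
library(molgcn)

cfg <- pipeline_config(
  sar  = sar_spec(n = 1000, seed = 42, noise_sd = 0.3),
  seed = 42, n_iter = 10, n_repeats = 2
)
report <- run_pipeline(cfg)
print(report)
#> Pipeline run report (seed 42 )
#>   compounds: 850 (train 679 / valid 86 / test 85)
#>   ensemble members: 4 of 4 candidates
#>   train  MAE 0.245  RMSE 0.354  R2 0.914  (individual MAE 0.279 +/- 0.020)
#>   valid  MAE 0.363  RMSE 0.546  R2 0.817  (individual MAE 0.396 +/- 0.016)
#>   test   MAE 0.368  RMSE 0.469  R2 0.769  (individual MAE 0.402 +/- 0.022)
#>   diversity: full H=2.61 KLD=0.001; train H=2.59 KLD=0.003; valid H=2.61 KLD=0.066; test H=2.59 KLD=0.095
#>   runtime: 160.2 s
```

Reading the numbers: 1000 raw rows shrink to 850 compounds because the
generator planted exactly 100 curation-violating rows and 50 duplicate
re-measurements, all caught by `build_dataset()`. The four search
candidates all reproduced their search-time validation R² after fixed-seed
retraining, so all four enter the ensemble. The ensemble's test-set MAE of
0.368 pIC50 units and R² of 0.769 clear the conventional good-model rule
(MAE < 0.6 or R² > 0.6) with a comfortable margin — and the ensemble beats
the average individual model (MAE 0.402 ± 0.022), as unweighted averaging
should. With noise σ = 0.3 the best achievable MAE is σ√(2/π) ≈ 0.24, so
the model has extracted most of the learnable signal. In the diversity
block, H ≈ 2.6 bits of a possible log2(15) = 3.91 says the compounds
concentrate in a few scaffold-size bins; the tiny training-set KLD and the
larger test-set KLD (0.095) quantify how much scaffold distribution shift
the random 10% split introduced.

Individual stages are ordinary functions with classed results — 
`build_dataset()`, `split_dataset()`, `gcn_fit()` (returns a `gcn_model`
with `predict`, `summary`, `plot`, `residuals` methods),
`search_hyperparameters()`, `gcn_ensemble()`, `carbon_skeleton()`,
`shannon_H()`, `kld()`, `screen()` — and a thin command-line front end with
`curate/split/simulate/diversity/screen/run` subcommands lives at
`inst/cli/molgcn.R`.

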