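# clockaudit

Tools for auditing sparse linear DNA-methylation (DNAm) age clocks.

Epigenetic clocks predict age (or an age proxy) as a weighted sum of CpG
methylation beta values, `ŷ = b + Σⱼ wⱼ βⱼ`, typically trained by elastic-net
(EN) regression on blood cohorts. `clockaudit` implements a battery of
diagnostics for what such clocks actually learn:

- **Coefficient-sign coherence audit.** A clock feature is *misaligned*
  (incoherent) when `sign(wⱼ) ≠ sign(rⱼ)`, where `rⱼ` is the CpG's univariate
  Pearson correlation with age in a healthy reference cohort. The audit
  reports the share of misaligned features and the share of total absolute
  model weight (`Σ|wⱼ|`) they carry, exports per-CpG tables with
  max-normalized coefficients, and *rectifies* models (dropping or
  sign-constraining misaligned CpGs), measuring the resulting trade-off
  between chronological-age accuracy (MAE) and healthy-vs-disease residual
  separation (standardized effect size of `ŷ − age` between groups).
- **Elastic net vs OLS under multicollinearity.** An in-package cyclic
  coordinate-descent EN (soft-thresholding, objective
  `(1/2n)‖y − b − Xw‖² + α(λ₁‖w‖₁ + (1−λ₁)/2 ‖w‖₂²)`, unpenalized
  intercept) with per-sweep objective tracking, an OLS fitter, the repeated
  80/20 split protocol, and a deliberately over-penalized "under-tuned"
  preset showing how EN zeroes collinear age-tracking CpGs and
  underpredicts older samples.
- **Leukocyte-composition dependence.** Reference-based deconvolution of
  bulk beta values into 12 immune cell fractions (nonnegative least squares
  + simplex renormalization), per-CpG Spearman correlations against each
  fraction, and the variance inflation factor audit: baseline
  `VIFⱼ = 1/(1 − R²ⱼ)` from regressing CpG j on the other model CpGs, the
  change ΔVIF after appending one cell-type fraction, binned at 0.025 /
  0.05 / 0.1 into small/moderate/large/very-large per cell type and model.
- **Noise barometer.** Per-CpG windowed mean/SD/CV across age, detection of
  loci with stable means but age-rising dispersion, and continuous
  piecewise-linear fitting (grid-searched free breakpoints) of the
  aggregate noise trajectory.
- **Synthetic cohort generator.** Seeded beta-value cohorts with the
  structure the audits assume — age-linear CpGs (0.008/year), exactly or
  noisily collinear CpGs, age-independent CpGs, mixture CpGs driven by a
  12-cell composition with declining naive T cells and a disease myeloid
  shift, and heteroscedastic noise following a piecewise SD-vs-age
  trajectory — with full ground truth retained, so every stage is testable
  without downloads.

## Worked example

```r
library(clockaudit)

# a 600-sample inflammaging cohort: half disease, disease samples look
# ~5 years "older" on age-tracking CpGs and carry a myeloid shift
cohort <- generate_cohort(inflammaging_cohort_spec(n_samples = 600, seed = 7))

# train an elastic-net clock and audit it against healthy-subset correlations
fit   <- fit_elastic_net(unclass(cohort$beta), cohort$metadata$age,
                         en_config(alpha = 0.1))
clock <- as_clock_model(fit, "demo_clock")
st    <- univariate_stats(cohort$beta, cohort$metadata, subset = "healthy-only")
audit_model(clock, st)
#> <coherence_report> demo_clock: 15/38 misaligned (39.5%), 23.1% of model weight

# rectify and measure the accuracy-vs-separation trade-off on held-out samples
trade <- tradeoff_experiment(cohort, seed = 42)
#> original:  MAE 3.90 y, healthy-vs-disease effect size d = 0.72
#> rectified: MAE 4.43 y, healthy-vs-disease effect size d = 1.59

# cell fractions and noise trajectory
est <- deconvolve(cohort$beta, cohort$reference_profiles)
mean(abs(est$fractions - cohort$true_fractions))   # 0.041
fit_noise_trajectory(windowed_noise(cohort$beta, cohort$metadata))
#> <trajectory_fit> breaks [38.0, 53.0, 59.0], slopes [...], R2 0.984
```

Reading: 39.5% of the trained clock's CpGs carry a coefficient whose sign
opposes their univariate age correlation, holding 23.1% of the model's
absolute weight. Dropping them costs 0.5 years of MAE but more than doubles
the healthy-vs-disease separation — the residual-cancelling features that
made the clock accurate also hid the disease signal. The fitted noise
trajectory recovers the planted rise/plateau/rise shape (true breaks at
36/48/60; window-grid resolution is 3 years).

## Command line

```sh
Rscript inst/cli/clockaudit.R demo --seed 1 --out out/
Rscript inst/cli/clockaudit.R simulate --config cfg.json --out out/
Rscript inst/cli/clockaudit.R audit --clock clock.tsv --beta beta.tsv \
    --meta meta.tsv --out out/
```

Subcommands: `simulate`, `train`, `audit`, `cellaudit`, `noise`, `demo`.
Configs are flat JSON (`validate_config()` lists every violation at once);
`demo` writes all figure-equivalent tables plus a hashed `manifest.json`,
byte-identical under a fixed seed.

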