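---
title: "Auditing linear DNAm age clocks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing linear DNAm age clocks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

DNA-methylation age clocks are sparse linear models: a prediction is an
intercept plus a weighted sum of CpG beta values (the methylated fraction at
a locus, in [0,1]). They are usually trained by elastic-net regression to
minimize the squared error of an age or age-proxy response. Minimizing
residuals is not the same as selecting biologically coherent features, and
this package implements four diagnostics for the gap:

1. **Sign coherence.** For each clock CpG, compare the sign of its model
   coefficient with the sign of its univariate Pearson correlation with age
   in a healthy reference cohort. Features whose signs disagree are
   *misaligned*: the model uses them in the direction opposite to their
   marginal age trend. We report both the count share and the share of
   total absolute weight carried by misaligned features, and we export
   per-model tables with coefficients max-normalized (divided by the
   largest |coefficient| in the model) for cross-model comparability.
2. **Rectification trade-off.** Removing (or sign-constraining) misaligned
   features yields an audit-clean model. On cohorts where some features
   carry disease signal that the fitter uses to *cancel* residuals, the
   rectified model separates healthy from disease residuals better while
   predicting chronological age worse. The package measures both sides on
   held-out samples.
3. **Leukocyte collinearity.** Bulk blood methylation reflects cell
   composition. We deconvolve per-sample fractions over 12 immune cell
   types, correlate each clock CpG with each fraction (Spearman), and
   quantify per-CpG multicollinearity attributable to each cell type as a
   change in variance inflation factor: baseline VIF from regressing the
   CpG on the other model CpGs, augmented VIF after appending one fraction.
4. **Noise barometer.** Some loci keep a nearly constant mean beta across
   age while their dispersion grows. We profile per-CpG mean/SD/CV in
   sliding age windows, flag stable-mean/rising-SD loci, and fit the
   aggregate dispersion trajectory with a continuous piecewise-linear model
   whose breakpoints are free parameters.

## The synthetic stated world

Every diagnostic is exercised on a seeded generator
(`generate_cohort()`), because the real cohorts behind such audits are
external downloads. The generator's defaults are the package's stated
world; they were fixed once and are not tuned to test outcomes.

- **Ages** are uniform on [20, 80] (configurable; an empirical-weights mode
  exists). The trajectory discussion that motivates the noise model spans
  roughly ages 25–80.
- **Age-linear CpGs** follow `beta = 0.008 × age + noise`; 0.008/year is
  the canonical didactic slope for an age-tracking CpG. The five-CpG
  didactic block (`generate_archetype_cpgs()`) adds a second independent
  copy, a CpG equal to half of the first (exactly collinear by default;
  a noisy mode exists because "collinear" can be read either way), and two
  age-independent CpGs (Gaussian and uniform). Constant archetype noise SD
  defaults to 0.04 beta-units — small enough that the age CpGs correlate
  strongly with age (r ≈ 0.9 at these settings), large enough that nothing
  is degenerate.
- **Cell mixture.** Twelve immune cell types (naive/memory CD4T and CD8T,
  naive/memory B, Treg, NK, monocytes, neutrophils, eosinophils,
  basophils — the standard blood-reference panel). Mean fractions are
  anchored at a realistic adult composition (neutrophils 45%, naive CD4T
  8%, ...), with naive T compartments declining ~0.1 percentage point per
  year and neutrophils stable; disease adds a lymphoid-to-myeloid shift
  (+4 pp neutrophils, +2 pp monocytes, −6 pp naive lymphoid). Realized
  fractions are Dirichlet draws (total concentration 200) around the
  adjusted means, which guarantees the simplex constraint with plausible
  inter-individual dispersion. Negative post-shift means (possible for the
  oldest disease samples) are floored at zero and renormalized, with a
  warning. Mixture CpG reference profiles are drawn uniformly on
  [0.1, 0.9] per cell type, which makes the 12 profiles linearly
  independent and mixtures identifiable given ≥ 12 shared CpGs.
- **Noise trajectory.** Per-CpG noise SD is piecewise-linear in age and
  continuous at the breakpoints: base 0.03 beta-units at age 20, rising at
  0.0015/year to 36, flat to 48, rising at 0.001/year to 60, flat after.
  The shape (rise, plateau, second rise) is stated qualitatively by the
  motivating analysis; the numbers are implementer-chosen so that windowed
  SD estimates at feasible cohort sizes resolve the breaks. SD (not
  variance) is linear per segment. Disease multiplies the SD by 1.5.
- **Inflammaging preset.** `inflammaging_cohort_spec()` plants a +5-year
  disease offset on the age-linear CpGs (disease samples read "older") and
  adds disease-archetype CpGs with a weak age slope (0.0015/year) but a
  strong additive disease shift (0.10 beta-units). These are the
  residual-cancelling features: a fitter that cannot observe the disease
  label can still use them, with weights whose sign opposes their healthy
  age correlation, to cancel the disease offset introduced through the
  age CpGs. That construction is exactly the precondition the trade-off
  experiment requires; rectification removes the cancellers and the
  disease signal reappears in the residuals.

What the generator does **not** emulate: array chemistry (IDAT
intensities, detection p-values), probe-level biases, genome coordinates,
batch effects, or non-blood tissue. A green test therefore establishes
that the audit arithmetic and the statistical machinery behave as
specified on data with the assumed structure — not that any particular
published clock has a particular misalignment percentage.

## Numerical choices

- **Elastic net.** Cyclic (not randomized) coordinate descent with
  soft-thresholding on internally standardized columns (mean 0, population
  SD 1), objective `(1/2n)·RSS + α(λ₁‖w‖₁ + (1−λ₁)/2‖w‖₂²)`, unpenalized
  intercept, coefficients un-scaled on output. Convergence when the
  largest absolute coefficient update in a sweep falls below `tol`
  (default 1e-6; `max_iter` 10000). Cyclic order and a deterministic
  objective trace make the fitter exactly reproducible, which the tests
  rely on (the per-sweep objective must be non-increasing). Constant
  columns are left at weight zero. The `"under-tuned"` preset is pure
  lasso (α = 2, λ₁ = 1): with any ridge admixture, exactly collinear
  standardized columns receive *equal* shared weights at the optimum, so
  only the pure-L1 penalty reproduces the demonstration in which a
  redundant collinear CpG is zeroed outright. The `"ols-like"` (α = 0.001)
  and `"lasso-heavy"` (λ₁ = 0.8) presets encode the two settings under
  which the penalty is effectively inactive.
- **OLS** solves the normal equations via QR and treats exact rank
  deficiency as an error naming the dependent columns — silently dropping
  a collinear clock CpG would hide precisely the phenomenon under audit.
- **Deconvolution** is nonnegative least squares (Lawson–Hanson active
  set, implemented in-package) followed by renormalization to the unit
  simplex. This is a documented stand-in for reference-based deconvolution
  tools whose exact robust-regression mode is out of scope; an `estimator`
  hook accepts alternatives. The audit downstream needs only consistent
  fraction estimates.
- **VIF.** Baseline predictors are the other CpGs of the same model only —
  no age, no fractions — because the audit isolates what adding *one*
  fraction changes. Perfect collinearity yields an `Inf` sentinel excluded
  from bins. Bin thresholds 0.025/0.05/0.1 are the quoted illustrative
  values and are config-exposed. When a model has more CpGs than a fifth
  of the samples, the audit runs on a seeded CpG subsample (logged): the
  regression would otherwise be saturated.
- **Coherence audit.** `neutral_band` defaults to 0: the comparison is a
  strict sign test, matching the definition of misalignment; a CpG with
  r exactly 0 is classified neutral so the sign product is never
  arbitrary. Weight shares use absolute coefficients (a "share of total
  weight" is only well defined on magnitudes). Model CpGs absent from the
  reference statistics are reported as `unmatched` and excluded from all
  denominators, never silently dropped. Univariate statistics default to
  the healthy-labeled subset, the conventional anchor for "direction of
  the univariate methylation change". Drop-mode rectification keeps the
  published weights and re-centers the intercept by default (refitting
  weights by OLS is optional); sign-constrained refitting solves a least
  squares problem with each weight constrained to the sign of its
  univariate correlation, via NNLS on sign-flipped columns (neutral CpGs
  enter in both orientations and are effectively unconstrained).
- **Noise barometer.** Windows default to width 6 years, step 3,
  minimum 20 samples (the motivating analysis anchors the trajectory at
  ages ~25/36/48/60 but states no window scheme; 6/3 resolves 12-year
  segments while keeping ≥ 100 samples per window at n = 2000). CV is
  undefined (NA, not 0) when the window mean is ≤ 0.05 beta-units —
  CV explodes near unmethylated loci. The aggregate trajectory statistic
  is the per-window median across CpGs of each CpG's z-scored windowed SD:
  robust to scale differences between loci, and configurable. Breakpoint
  search is exhaustive over interior window midpoints (deterministic,
  ≤ 3 breaks at desk scale); segment slopes come from the truncated-power
  basis, so the fit is continuous by construction.
- **Determinism.** A single run seed is expanded into per-stage substreams
  by a fixed affine map modulo 2^31 − 1 (`derive_seed()`), so stages
  reproduce in isolation; all file output uses fixed 15-significant-digit
  formatting, making demo reruns byte-identical (hashed in the manifest).

## Known limitations

- The rectification implemented here (drop or sign-constrain) is a
  simplified stand-in for full incoherence-rectified retraining; it
  preserves the audit postcondition (no misaligned features) but not any
  particular retraining algorithm's selection path.
- The trade-off direction (separation up, accuracy down after
  rectification) is a property of cohorts containing residual-cancelling
  disease features. On cohorts without planted disease structure both
  separations are near zero, and the experiment says nothing.
- Breakpoint estimates are grid-limited to window midpoints; with the
  default 3-year step the resolution is ±1.5 years before sampling error.
- The deconvolution stand-in assumes the reference profiles span the
  samples; residual norms are reported per sample but no goodness-of-fit
  test is performed.
- Published clocks applied through `apply_clock()` are audited exactly as
  given; per-clock missing-probe policies of the original publications are
  not modeled (the package's zero/error/mean-impute policies are generic).
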