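---
title: "Models and methods behind plexda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plexda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistics: the model that
is fitted per protein, the numerical choices inside the fitting engine, what
the spike-in simulator does and does not emulate, and the design decisions
taken where several defensible conventions exist.

## The data and their correlation structure

Isobaric labeling quantifies a protein through the reporter ions of its
identified spectra. One spectrum yields intensities for *all* channels of its
run simultaneously, so intensities within a spectrum share identification
and fragmentation conditions; intensities within a sample (a run × channel
pair) share a protein pool; intensities within a run share instrument state;
and runs within a mixture share the labeled pool. `plexda` represents this
as a features-by-samples matrix (`feature_assay`) in which a spectrum row is
observed only in its own run's columns — the block-missing structure is
real, not an artifact — plus a sample annotation with `run`, `channel`,
`mixture`, `bio_replicate`, `tech_rep`, `is_reference` and arbitrary
condition columns.

## Per-protein model

For one protein, the log2-transformed and normalized intensities are
modeled as

$$ y = X\beta + Zu + \varepsilon, \qquad u \sim N(0, \sigma^2 G), \qquad
   \varepsilon_i \sim N(0, \sigma^2 / w_i), $$

with $G$ block-diagonal: one variance ratio $\gamma_b = \sigma_b^2/\sigma^2$
per term. Random intercept terms encode the grouping hierarchy (`run`,
`mixture`, `sample = run:channel`, `psm = spectrum`); at the protein level
the spectrum and sample terms disappear because summarization has already
absorbed them. Condition effects can be placed either in $X$ (fixed,
cell-means coding `~ 0 + condition` so that all pairwise contrasts resolve)
or in $Z$ as a *ridge block*: the full set of condition indicators, no
reference level dropped, sharing one variance component. The REML estimate
of that component's ratio determines the ridge penalty
$\lambda = 1/\hat\gamma$ adaptively per protein. Keeping all levels in the
block shrinks every condition effect symmetrically toward zero, which is
what produces near-zero log2 fold changes — and hence p-values piling up at
1 — for proteins without a real signal, while the intercept stays
unpenalized.

### REML estimation

Variance ratios are profiled on the log scale with bounded derivative-free
searches (golden-section for one ratio, Nelder–Mead with box clamping for
several; ratios live in $[10^{-10}, 10^{8}]$). The residual variance is
profiled out analytically, so the objective is
$\log|V| + \log|X'V^{-1}X| + (n-p)\log(y'Py)$ with
$V = W^{-1} + \sum_b \gamma_b Z_b Z_b'$. Each evaluation runs through the
Woodbury identity on weighted cross-products precomputed once per fit
(compiled in C++), so the cost per evaluation is cubic in the number of
block columns, never in the number of observations. At the optimum the
mixed-model (Henderson) equations deliver all coefficients — fixed
estimates and shrunken block effects — and their unscaled covariance
$C^{-1}$; this covariance is what Wald tests on penalized coefficients use.
A ratio estimated at the floor of $10^{-10}$ marks its block as effectively
zero (recorded in the fit's message); a non-solvable system raises a typed
`SingularFit` error rather than silently degrading.

The balanced one-way layout has closed-form REML estimators
($\hat\sigma^2 = \mathrm{MSW}$,
$\hat\sigma_u^2 = \max(0, (\mathrm{MSB}-\mathrm{MSW})/n)$); the test suite
checks agreement to $10^{-6}$ relative on 50 random layouts, cross-checks a
crossed two-factor design against lme4, and verifies that a pinned-ratio
ridge block reproduces $(X'X + \lambda I)^{-1}X'y$ to $10^{-8}$.

### Robustness

With `robust = TRUE` (the default in the named workflows), fitting is
iteratively reweighted REML: residuals from the current fit are standardized
by a robust scale — the median absolute deviation with the usual 1.4826
consistency factor, recomputed every iteration — and mapped through the
Huber weight $w_i = \min(1, k/|r_i/s|)$ with $k = 1.345$, the constant
giving 95% efficiency under Gaussian errors. Iteration stops when the
largest coefficient change drops below $10^{-6}$ or after 20 rounds; the
variance-ratio search warm-starts from the previous iteration. The choice
of $k$ and of the MAD scale are package conventions: they are the standard
ones for Huber M-estimation, and nothing in the workflows depends on their
exact values beyond the usual efficiency/robustness trade-off.

### Effective degrees of freedom

The moderated tests need a residual degrees-of-freedom number for fits that
mix fixed, shrunken and ridge-penalized effects. The package uses the
hat-matrix trace: $\mathrm{df} = \sum_i w_i - \mathrm{tr}(H)$ with
$H = T C^{-1} T' W$ over the full solve ($T = [X\; Z]$), clipped to
$[1, n-1]$. This interpolates correctly between the two limits — a block
with vanishing variance contributes nothing, a block with huge variance
behaves like fixed columns — and reduces exactly to $n - p$ for ordinary
regression. This is a declared design decision: other conventions
(Satterthwaite, Kenward–Roger) exist and are out of scope.

### Moderation and inference

Per-protein residual variances are pooled with the standard empirical-Bayes
scaled-F moment matching on log variances (delegated to limma's
`fitFDist`); when the observed dispersion does not exceed the chi-square
sampling noise the prior degrees of freedom are infinite and all posterior
variances collapse to the common value. Posterior variances follow
$s^2_{\text{post}} = (d_0 s_0^2 + \mathrm{df}\, s^2)/(d_0 + \mathrm{df})$.
Wald tests on contrasts $L$ use
$t = L'\hat\beta \big/ \sqrt{L' C^{-1} L\, s^2_{\text{post}}}$ on
$d_0 + \mathrm{df}$ degrees of freedom (capped at $10^6$ when $d_0$ is
infinite, i.e. effectively normal). Benjamini–Hochberg adjustment is applied
per contrast across the proteins with successful fits only; proteins whose
fit failed are excluded from the multiplicity count, matching how
per-comparison results are reported in practice. Whether adjustment should
instead pool all contrasts is genuinely open; per contrast was chosen
because each contrast answers a separate scientific question.

## Preprocessing and summarization conventions

* Channel-median normalization subtracts each sample's observed median log2
  intensity; medians use observed values only, and a channel left empty
  raises rather than silently producing zeros. It assumes most proteins are
  not differentially abundant — the spike-in simulations in this package
  show the footprint of violating it (a small negative bias on null
  proteins when all spiked proteins move the same way). Whether the median
  is taken per run or globally is configurable (`scope`); for column-wise
  medians the two coincide, and `per_run` is the default.
* Reference normalization subtracts, per run and per feature, the median
  across that run's reference channels.
* Zero reporter intensities are mapped to missing on import by default
  (`zero_is_missing`), since a zero reporter ion is non-physical.
* Median polish sweeps rows first, then columns, folding the medians of the
  effect vectors into the overall term after each pair of sweeps; medians of
  an even count are the mean of the two central values. Only fitted values
  and effect differences are contractual — the split between overall and
  effects is convention. Iteration stops when the L1 residual change falls
  below `tol * (1 + L1 of data)` (`tol = 1e-6`, `max_iter = 100`);
  non-convergence (possible oscillation with missing cells) is flagged but
  the result is returned. Protein abundance per sample is
  `overall + column effect`.
* Per-mixture summarization stacks the spectra of all fraction runs of a
  mixture as extra rows over the shared channels — fractions measure the
  same samples, so rows, not extra columns, is the coherent layout.
* The spike-in-specific multibatch normalization (correlation filter at
  0.25, summed signal-to-noise filter at 20, per-run geometric-mean
  centering on the 50% most stable background features) treats correlations
  computed from fewer than 3 complete pairs, or from constant features, as
  0: the rule removes features, and insufficient evidence should not
  remove. Ties at the stability cutoff break by feature id for determinism.
* No imputation anywhere by default; `impute_with()` accepts a user
  function for those who want it.

## One-hit wonders and the refit fallback

A protein with a single spectrum per run gives every sample (run × channel)
exactly one observation, so the sample-level random term is confounded with
the residual; the same applies to the spectrum term when every spectrum is
observed once. `detect_one_hit_wonder()` flags exactly this condition
(every level of a grouping factor holding at most one observation). The
strict PSM workflow reports such proteins as `fit_failed` — an explicit
error is more transparent than silently fitting a different model — while
`run_psm_rrilmm_refit()` retries them under `reduce_model()`, which drops
confounded random terms in a fixed order (spectrum first, then sample, then
the rest) and marks the results `reduced`.

## What the simulator emulates — and what it does not

`simulate_spikein()` generates the hierarchy the model describes: protein
and peptide log2 baselines, one spectrum per peptide ion per run, Gaussian
mixture/run/sample/spectrum effects *drawn per protein* (the model's random
effects are protein-specific deviations; experiment-wide loading shifts are
a normalization matter), condition offsets for spiked proteins
(`delta * condition_profile`, reference channels receiving the
condition-average), logistic missing-at-random dropout driven by the
peptide baseline (low-abundance biased; slope 0 gives a
completely-at-random ablation), and symmetric additive log2 outliers.
Spectrum counts are zero-truncated Poisson, so one-hit wonders occur
naturally. The default template mirrors a classic TMT10 spike-in: five
mixtures of ten channels, two reference channels, four conditions of two
channels whose profile follows the dilution series 1, 0.667, 0.5, 0.125,
90% background proteins, and variance components
(run 0.3, mixture 0.1, sample 0.2, spectrum 0.5, residual 0.25 on the log2
scale, peptide spread 1, baseline 16 ± 1.5) chosen as plausible for
reporter-ion data; no published numeric values exist for them, so they are
calibration, not ground truth.

Deliberately *not* simulated: ratio compression from co-fragmentation
interference (real spike-in studies underestimate large fold changes; the
simulator is attenuation-free, which is precisely what makes it usable as a
recovery oracle), identification errors, and intensity-dependent variance.
Passing tests therefore demonstrate that the estimators recover the model
they assume, and that robustness and shrinkage behave as designed under
contamination — not that real TMT data meet these assumptions.

## Problem sizes used by the test suite

The simulation studies in the tests use: 20 seeds × 2000 proteins for
null-data FDR calibration of the non-ridge protein workflow; 20 seeds × 200
proteins with 10% outlier cells of magnitude 5 log2 units for the
robust-ridge dominance comparison; 100 proteins at spectrum mean 2 for the
one-hit-wonder refit; 800 proteins for the ridge shrinkage signature; and
500 proteins × 10 mixtures for variance-component recovery (medians of the
per-protein estimates are compared to the truth, since individual REML
estimates from a handful of runs are intrinsically noisy). These sizes give
stable pass/fail behavior for the properties being checked while keeping
the default test run in the minutes range.

## Known limitations

* Random terms are independent intercept blocks; crossed correlation
  structures inside $G$, random slopes, and non-Gaussian responses are out
  of scope.
* The effective-df convention is a choice, not an estimate of the true
  sampling df; small-sample p-values inherit its approximation.
* BH control is per contrast; no q-value/π₀ estimation is provided.
* The simulator's missingness is MAR given peptide baseline; informative
  (MNAR) censoring common in low-abundance reporter ions is not modeled,
  which is consistent with the workflows' decision not to impute.
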