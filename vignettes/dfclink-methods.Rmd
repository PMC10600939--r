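---
title: "Linking connectivity dynamics to behavioral and cognitive dimensions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking connectivity dynamics to behavioral and cognitive dimensions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dfclink` implements a multivariate pipeline relating the *temporal
variability* of resting-state functional connectivity to behavioral and
cognitive dimensions, together with a synthetic-cohort generator that
plants known structure so every stage can be validated by parameter
recovery. This vignette is the package's account of the science: the
models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not establish.

## The dFC variability measure

Each subject contributes a parcellated time series (time points x ROIs;
the default design assumes 200 volumes at TR = 2 s and a 227-ROI atlas
whose regions belong to ten large-scale networks). A rectangular window
of 22 TR (44 s) slides in steps of 1 TR, giving
`floor((200 - 22)/1) + 1 = 179` windows; within each window the Pearson
correlation of every ROI pair is computed. The dynamic functional
connectivity (dFC) value of an edge is the *sample standard deviation*
(denominator `n - 1`) of its windowed correlations — higher values mean
less stable coupling over time. Choices worth stating:

* **Rectangular, untapered windows.** The plain sliding window is the
  default in the toolboxes this analysis style comes from; tapers are a
  sensitivity analysis we deliberately leave out of scope.
* **SD on the raw correlation scale.** A `fisher_z = TRUE` switch
  applies `atanh` first for sensitivity analyses; the default is the raw
  scale because the SD-of-correlations construct is defined on it.
* **Window width trade-off.** For stationary data the expected SD is
  pure sampling noise and shrinks as windows widen; the test suite
  checks this monotonicity over widths 11/22/44 TR. Width 22 TR at
  TR = 2 s sits in the 30-60 s range generally considered able to
  resolve resting-state fluctuations.

As a methodological cross-check, `fls_dfc()` re-estimates edgewise
variability by flexible least squares (FLS): for standardized series
`x, y` it finds the time-varying coefficient path minimizing

$$\sum_t (y_t - \beta_t x_t)^2 + \mu \sum_t (\beta_{t+1} - \beta_t)^2,$$

solved exactly through the tridiagonal normal equations (a vectorized
Thomas sweep across all edges), and summarizes the path by its SD. With
large penalty the path collapses to the static OLS slope (SD tends to 0);
with `mu = 0` it is the pointwise ratio. The default `mu = 100` (on
standardized series) gives paths smooth at the timescale of tens of TRs;
on synthetic cohorts with planted dynamics the edgewise agreement
between FLS and sliding-window estimates is `r` well above 0.5, which is
the property the cross-check is meant to establish.

## Confound handling and feature reduction

Age, sex (0/1) and mean framewise displacement are removed from the dFC
features, and age and sex from the clinical items, by OLS
residualization on an intercept plus the named covariates
(`residualize()`); residuals are exactly uncorrelated with every
covariate used, and residualization is idempotent.

The edge space (25,651 features at 227 ROIs) is reduced by the Relief
family (`relief_weights()`): ReliefF against a class label, or RReliefF
against a continuous target, with Manhattan-distance neighbourhoods on
range-normalized features. The pipeline's default supervising target is
the first principal component of the (residualized) clinical block being
analyzed, so selection sees the same clinical domain as the subsequent
sparse CCA; ReliefF against the diagnosis label is available as the
classification alternative. The top 1% of features by weight
(`select_top_fraction()`, ceiling rule, ascending-id tie break) enter
the model. PCA reduction to a target explained-variance fraction
(`pca_reduce()`) is provided as the alternative reduction route.

**Neighbourhood size.** Relief weights estimate, roughly, how much a
feature's differences co-occur with target differences among near
neighbours; that signal grows ~quadratically with the feature-target
correlation, so at the modest per-edge correlations realistic for dFC
(|r| ~ 0.3-0.5) small neighbourhoods are dominated by noise. The
pipeline therefore defaults to a near-cohort neighbourhood
(`k_neighbors = 100`, clamped to n-1, with mild rank-decayed influence,
`sigma = k`); `relief_weights()` itself defaults to the conventional
k = 10 for users who want the textbook estimator.

## Sparse canonical correlation by penalized matrix decomposition

`fit_pmd_pair()` finds weight vectors maximizing `cor(Xu, Yv)` under
unit L2 norms and L1 budgets `||u||_1 <= c_x * sqrt(p)` (likewise for
`v`) — the rank-one penalized matrix decomposition (PMD) of the
cross-product `X'Y`, i.e. diagonal-penalized sparse CCA with an
elastic-net-like constraint (L1 budget plus implicit L2). Numerics:

* alternating soft-threshold updates with the threshold found by
  bisection on the L1 norm of the L2-normalized vector;
* deterministic initialization from the leading right singular vector
  of `X'Y` (sign-fixed), so fits are reproducible;
* `tol = 1e-6` on the weight-vector sup-norm change, `max_iter = 200`;
* the feasible L1 budget is clamped to `[1, sqrt(dim)]` — a unit-L2
  vector cannot have L1 below 1;
* sign convention: the pair is flipped so the canonical correlation is
  non-negative.

Successive pairs come from rank-one deflation
(`X <- X - (Xu)u'`, same for Y) without re-standardization
(`fit_scca()`); a sparse `u` annihilates its own columns exactly, so
deflated refits tolerate zero columns.

Because PMD penalizes the *diagonal approximation* of the within-block
covariances, its unpenalized limit equals classical CCA exactly only
when the block covariances are the identity; the oracle-equivalence
tests therefore run on column-whitened instances, where agreement to
1e-6 is the correct mathematical statement.

Sparsity budgets default to `c_x = 0.7`, `c_y = 0.8`; `tune = TRUE`
replaces them by a grid search maximizing the first-pair canonical
correlation estimated out of sample by 5-fold cross-validation on
subjects (ties resolved toward the sparser cell).

## Inference

* **Permutation test** (`permutation_test()`): subject rows of the
  clinical block are permuted; the full model (same budgets, same
  number of pairs) is refitted; `p = (1 + #{r_perm >= r_obs}) /
  (1 + n_perm)` (add-one form, so p is never 0). By default the Relief
  selection is *not* re-run inside permutations, matching common
  practice and desk-scale runtime — but this is anticonservative under
  the null whenever selection is supervised, because the observed fit
  enjoys a selection the permuted fits do not earn. The
  `reselect_in_permutation` option (and the `X_full`/`select_fun`
  arguments) re-runs selection per permutation, and the null-soundness
  test uses it. A second small-sample caveat: residualized rows are
  only asymptotically exchangeable, so at very small n (a few dozen
  subjects with several covariates) the left tail inflates slightly;
  calibration is tested at the cohort sizes the pipeline targets.
* **FDR**: Benjamini-Hochberg across the extracted pairs; in `run_all()`
  the behavior-block and cognition-block pairs are corrected *jointly*.
* **Bootstrap stability** (`bootstrap_stability()`): subjects resampled
  with replacement, model refitted, each pair sign-aligned to the
  original `u`; a feature is *stable* ("reliable") when it is selected
  with its original sign in at least `stability_threshold = 0.9` of
  resamples. Canonical-correlation mean and SE over resamples are
  reported per pair. Degenerate resamples (zero-variance columns) are
  redrawn and counted.
* **Structure loadings** (`structure_loadings()`): the Pearson
  correlation of each original variable with its own side's canonical
  variate. Network-level summaries (`network_block_loadings()`) are sums
  of absolute loadings within each of the 55 within/between-network
  blocks of a 10-network atlas, with absent edges contributing zero.

## Mediation

When a behavior dimension and a cognition dimension are both
FDR-significant, their stable dFC feature sets are intersected; the
overlap is split by the sign of the cognition-side loading into
"positive links" and "negative links", each summarized per subject as
the mean dFC over its edges (`select_overlap_composites()`).
`fit_mediation()` then estimates dFC -> cognition -> behavior by three
OLS fits (`M ~ X + covs`, `Y ~ X + M + covs`, `Y ~ X + covs`, with age
and sex entered as regressors), giving paths `a`, `b`, the direct
effect `c'`, the indirect effect `IE = a·b` and the total effect, with
`TE = c' + IE` holding exactly for this linear specification on a
common case set. Confidence intervals are percentile bootstrap over
subjects (default 5000 resamples); the proportion mediated `IE/TE` is a
ratio of point estimates and is reported without a significance flag
(its bootstrap distribution is unstable near small `TE`, and it is
undefined when `TE` is numerically zero). The pipeline standardizes the
composite and both dimension scores first, so the reported paths are on
the standardized scale.

## The synthetic cohort: what it emulates

`simulate_cohort()` generates the study conditions end to end: a
227-ROI/10-network atlas (counts mirroring a standard functional
parcellation after dropping unassigned and cerebellar nodes; other
sizes by largest-remainder scaling), 122 subjects of whom 63 are
labelled patient-like (the subjects with the highest behavior-problem
latent scores), 200 TR at TR = 2 s, signals band-limited to
0.01-0.08 Hz by frequency-domain masking of the driving noise before
covariance coloring, and a clinical table of parent-rating-style
behavior items and cognitive test scores with planted loadings, age
slopes and a small sex shift.

Connectivity dynamics follow a two-state regime-switching correlation
process with geometric dwell times (mean 20 TR). Two latent dimensions
(behavior problems; cognition, correlated -0.4) each couple to a sparse
random edge set (0.5% of edges); a coupled edge's between-regime
correlation gap is

$$g_e(s) = g_0 + \kappa \,\sigma_e \, z_d(s) + \text{nuisance}(age, motion),$$

floored at a small positive value and clipped so state correlations stay
inside (-1, 1), with PSD repair by eigenvalue flooring where needed.
Half of each dimension's edges are shared with the other dimension, with
coherent signs (an edge loading positively on behavior problems loads
negatively on cognition when the latents are anticorrelated) — this is
what makes the downstream overlap/mediation stage recoverable.

Two calibration choices deserve explanation, both fixed at design time:

* **Operating gap `g_0 = 0.9`, coupling slope `kappa = 0.4`.** Hard
  band-limiting to 0.01-0.08 Hz leaves ~29 Fourier components in 200 TR,
  so windowed correlations carry a large sampling floor (null-edge
  dFC-SD ~0.36) and the SD-vs-gap response is quadratic near zero; a
  higher operating gap linearizes the latent-to-variability map so that
  a slope of 0.4 produces per-edge correlations (~0.4-0.5) in the range
  where selection and recovery are informative rather than trivially
  impossible.
* **Cohort-shared regime chain** (`shared_chain = TRUE`). With ~10
  regime segments per run, independent chains add large state-occupancy
  noise across subjects that has nothing to do with the planted
  amplitudes; sharing one chain isolates the planted signal. Real
  subjects of course do not share switching times —
  `shared_chain = FALSE` restores per-subject chains for realism-first
  experiments.

One consequence of this design is worth knowing when reading pipeline
output: because the shared edges track the behavior-cognition *contrast*,
the overlap composite already carries most of the cognition information,
and the partial coefficient of the cognition score given the composite
(the mediation `b` path) is analytically small (~-0.1 at the default
scales). The pipeline's mediation stage therefore reports a small,
usually non-significant indirect effect on default synthetic cohorts —
the correct answer for this generative structure, not a failure of the
estimator. Planted-path mediation recovery is validated separately with
`simulate_mediation_cohort()`, which generates the exact three-equation
structural model with known `a`, `b`, `c'`.

What passing the recovery suite shows: that the pipeline, run end to
end at the emulated scale, finds the planted dimension (FDR-significant
first pair whose weight vector aligns with the planted edge pattern),
recovers shared edges into the overlap composites, and estimates planted
mediation paths with calibrated bootstrap intervals. What it does not
show: performance on real BOLD data, whose noise is not Gaussian or
brickwall-band-limited, whose confounds are not three well-behaved
covariates, and whose effect sizes are unknown — the generator's scales
are chosen for testability, not as claims about the brain.

## Problem sizes used in validation

Tests and the acceptance script run scaled-down but structurally
faithful versions of the design: recovery at 64 ROIs (2,016 edges) with
the full 122 subjects and 200 TR over 10 seeds; null calibration with
200 replicates of n = 60, 50 post-selection features, 99 permutations;
mediation recovery with 50 replicates of n = 500 and 500-resample
bootstraps; null-soundness uniformity on 60 ten-ROI cohorts with
selection re-run inside each permutation. The full 227-ROI cohort runs
through the same code path (`make_atlas()` defaults) in tens of minutes
on one core.

## Known limitations

* Diagonal-penalized sCCA ignores within-block covariance; on strongly
  collinear features the first pair maximizes covariance, not
  correlation, and can differ from classical CCA by design.
* Fixed supervised selection inside permutation (the default) inflates
  significance under the null; use `reselect_in_permutation = TRUE`
  when the claim being tested is the whole-procedure significance.
* The proportion mediated is a point-estimate ratio; treat it as a
  descriptive diagnostic.
* The FLS smoothness penalty is reported per standardized series; its
  scale is not comparable across different standardizations.
* BH adjustment is applied to the extracted pairs of two models jointly;
  with many extracted pairs most of which are noise, this is
  conservative for the leading pairs.
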