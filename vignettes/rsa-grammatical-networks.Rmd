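---
title: "Methods: representational similarity analysis of grammatical processing networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity analysis of grammatical processing networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsagram)
```

## The analysis in one paragraph

For each subject and region of interest (ROI), the pipeline takes a
voxel × condition matrix of GLM parameter estimates for the 12
conditions of the grammatical design (3 sequence types — bare stem,
inflected form, minimal phrase — crossed with 4 verb/noun dominance
categories), and computes an activation representational dissimilarity
matrix (RDM) whose cells are correlation distances `1 − r` (Pearson
across voxels). RDMs are averaged across participants per region and
compared against hypothesis model RDMs by a second-order rank
correlation restricted to the cells each model constrains. Significance
comes from a condition-label permutation null; false discovery rate is
controlled across the regions tested within each model family; model
pairs are compared by subject-level sign-flip tests; and the joint
region–model geometry is summarized by classical multidimensional
scaling.

## First-order distances and their assumptions

`correlation_distance()` is `1 − r` and therefore lives in `[0, 2]`: 0
for perfectly correlated patterns, 1 for unrelated patterns, 2 for
perfect anticorrelation. Pearson `r` is invariant to positive affine
rescaling of each condition's pattern, which is why no voxel-wise
normalization is applied before the distance: any per-condition
scaling or offset introduced upstream (e.g. by GLM scaling conventions)
cancels. The property-based tests assert this invariance directly, as
well as the antipodal identity `d → 2 − d` when one pattern is negated.

A condition pattern that is constant across voxels has no defined
correlation. Rather than emitting `NaN` — which would silently poison a
group average — the package raises a *degenerate pattern* error naming
the condition, and the pipeline (`fit_models()`) drops that
subject/ROI with a logged warning and proceeds. Averaging order
follows the standard group-RSA convention: average RDMs across
subjects, then correlate with models. Per-subject model statistics are
additionally retained, because the model-comparison test needs
within-study variability.

## Model RDMs and the meaning of unconstrained cells

The five standard models are built from the condition set rather than
hard-coded, so the cell semantics are explicit:

* `general_complexity_model()` — two-class categorical: 0 within
  {inflected ∪ phrase} and within {stem}, 1 across. Stem–stem cells
  are constrained to 0 by default; this is the canonical two-class
  "category present" rank-correlation test. A switch
  (`constrain_stem_pairs = FALSE`) leaves them unconstrained for users
  who prefer a model silent about stem-internal structure.
* `complexity_type_model()` — three-class categorical: 0 within each
  sequence type, 1 between types.
* `detector_model(target)` — 0 within the target type, 1 from target
  to everything else, and **unconstrained** (`NA`) among non-target
  conditions. A detector claims only that its target dominates; it
  should be agnostic about what the other conditions do among
  themselves. Users wanting a fully constrained variant can set
  `nontarget_value = 0.5`.
* `dominance_modulated_detector(target)` — within-target cells graded
  as `|wᵢ − wⱼ|` with the dominance weights (1.0, 0.84, 0.06, 0.0),
  which groups the two verb sets (mutual dissimilarity 0.16) apart
  from the two noun sets (0.06) while keeping the verb–noun contrast
  near 1. The absolute difference is the simplest metric with this
  grouping behaviour; multiplicative alternatives (e.g. `1 − wᵢwⱼ`)
  would also work but add nothing for rank-based statistics.

Condition ordering is fixed — types-major (stem, inflected, phrase),
categories in the order verb-unique, verb-dominant, noun-dominant,
noun-unique — so RDM cell indices are stable across exports, fixtures
and user-supplied TSV models.

## Second-order statistics and inference

The default statistic is Spearman rank correlation over the model's
constrained upper-triangle cells (the default because it is insensitive to
any monotone miscalibration between predicted and observed
dissimilarities). Kendall's τₐ — pair counting with the full
`n(n−1)/2` denominator, no tie correction — is provided because
categorical model RDMs are heavily tied, and τₐ is the recommended
rank statistic in that regime; base R's Kendall implementation is
tau-b, so τₐ is implemented directly and verified against an
exhaustive pair-count oracle.

The permutation null randomizes condition labels: one random
permutation is applied simultaneously to rows and columns of the data
RDM and the statistic is recomputed; `n_perm` defaults to 10,000 with a
mandatory seed. The p-value uses the add-one estimator
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`, which is strictly
positive and exactly valid under the null; ties count toward the null
(with a `1e−12` tolerance so floating-point noise cannot turn a tie
into a win). Tests are one-sided — a model fit is a *positive*
correlation — matching the directional hypotheses the models encode.

Model comparison (`compare_models()`) computes per-subject statistic
differences `dₛ = statA(s) − statB(s)`, each model on its own
constrained cells, and tests the mean against zero by sign flipping:
exhaustive over all `2^S` assignments for `S ≤ 12` subjects, Monte
Carlo beyond. This is a deliberate reconstruction: the original
better-fit test is not specified in enough detail to copy, and the
sign-flip test is the standard exact choice for paired second-order
statistics.

## FDR: Storey q-values

`storey_qvalues()` estimates the null proportion π₀ from
`π₀(λ) = #{p > λ} / (m(1 − λ))` on a λ grid (default 0.05…0.95). With
`m ≥ 100` the grid estimates are smoothed by a natural cubic spline
(df = 3) and read off at the largest λ. With small families — the
pipeline's own use is m = 22 regions per model — the tail counts
behind the smoother are 0–2 p-values and the extrapolation is wildly
unstable, so the estimator falls back to the single-λ estimate nearest
λ = 0.5, the original and most robust choice. π₀ is clamped to
`[1/m, 1]`. Q-values are the running minimum of `π₀ m p(i) / i` over
the sorted p-values, hence monotone in p. Calibration is verified by
simulation: on mixtures with π₀ = 0.8, m = 1000, the realized FDR at
q ≤ 0.05 stays at the nominal level and the π₀ estimate is unbiased to
within ±0.1. `bh_fdr()` (step-up via `p.adjust`) is the simpler
fallback, selectable in the pipeline config.

## Region–model geometry and MDS

`model_region_distances()` builds `1 − correlation` distances among
regions (full upper triangles) and models (region–model on the model's
constrained cells, identical to the fitted statistic). Model–model
cells are computed on jointly constrained cells; for two detector
models that intersection is the constant-1 cross-class block, whose
correlation is undefined — the function errors naming the pair, and
offers `model_pairs = "neutral"` (used by the pipeline) which fills
unconstrained cells of both models with a neutral 0.5 for model–model
cells only.

`classical_mds()` wraps the Torgerson double-centering
eigendecomposition (`stats::cmdscale`) and adds a canonical
orientation — axes ordered by eigenvalue, each axis's sign fixed so the
entity with the largest absolute loading (lexicographically first
label on ties) loads positively — so embeddings are reproducible and
order-invariant. Because any 2-D projection of a higher-dimensional
geometry distorts some pairs, the output includes per-pair residuals
(embedded minus input distance) and their RMS as a stress summary,
rather than hiding distortion in a plot aesthetic. Exactly
2-D-embeddable inputs are reproduced to `1e−8`.

## The synthetic study: what it emulates and what it does not

`simulate_study()` emulates the study conditions the pipeline targets:
18 subjects, 22 ROIs ({BA44, BA45, BA47, FOP, aSTG, pSTG, aMTG, pMTG,
aITG, pITG, TP} × {L, R}), 12 conditions, per-ROI voxel counts drawn
log-uniformly in [50, 500] (fixed by seed — anatomical ROI volumes
span roughly this order of magnitude on a 3 mm grid). The default
planted scenario mirrors the topography the detector analysis is
designed to resolve: the inflection detector in L BA44, L pSTG and
L aITG; the phrase detector in bilateral aSTG/aMTG and L pMTG; all
other regions pure noise.

Generation bridges a model RDM to a condition covariance:
`S = 1 − dissim` on constrained cells, diagonal 1, and
`Σ = αS + (1 − α)I` clipped to positive semidefinite (default
α = 0.5). Each voxel's 12-condition signal row is i.i.d. `N(0, Σ)`,
scaled so signal variance / unit noise variance equals `snr` (study
default 5, a strong but not saturated planted geometry: the
asymptotic within-target pattern correlation is
`snr·α/(snr+1) ≈ 0.42`).

Cells a model leaves unconstrained generate **independent** patterns
(`unconstrained_similarity = 0`). An intermediate similarity (say 0.5)
looks superficially more "neutral", but it induces graded structure
among non-target conditions that a fully constrained categorical model
partially predicts; under Spearman the planted detector is then
tie-capped at a statistic of ≈ 0.632 while the complexity-type model
reaches ≈ 0.655 on the detector's *own* geometry, making the planted
model unidentifiable. With independent non-target patterns the planted
detector attains Spearman 1.0 asymptotically and recovery is clean.
The parameter is exposed for users who want to study exactly this
failure mode.

What the generator does **not** emulate: spatial noise correlation
(voxel noise is i.i.d.; smoothness mainly rescales effective voxel
counts for correlation-based RDMs, but users extending to
searchlight-style analyses should add it), inter-subject geometric
variability beyond noise (every subject shares Σ), hemodynamic or
trial-level structure (generation starts at the GLM-beta level, the
pipeline's actual input), and anatomically realistic ROI shapes (the
NIfTI export places ROIs in disjoint blocks of a 3 mm grid). Passing
tests therefore demonstrate the *statistical machinery* is correct and
calibrated, not that real fMRI data will show these effect sizes.

## Volumetric conventions

Voxel indices are 1-based R array indices; the NIfTI affine applies to
the 0-based index per the NIfTI convention, so world coordinates are
`A·(i−1, j−1, k−1, 1)ᵀ` in MNI mm. Sphere ROIs (`make_sphere_roi()`,
e.g. the frontal operculum as a 10 mm sphere at (−36, 20, −3), mirrored
at (36, 20, −3)) include voxels whose *centers* fall within the radius
— no partial-volume weighting. The anterior/posterior split of the
temporal gyri uses a world-y boundary; no standard cut coordinate
exists, so the default is the mask's own median y (balanced halves per
region), configurable to a fixed coordinate, and the choice is recorded
in the run manifest. Masks and condition images must share one grid;
native-space inverse normalization is out of scope and the synthetic
export guarantees a shared grid.

## Determinism and problem sizes

Every stochastic step takes a seed; the pipeline derives per-test
permutation seeds from the run seed by name-addressed lookup, so
results are independent of region iteration order and reruns are
byte-identical (asserted on the TSV outputs). The test suite verifies,
among others: exactness of distances and rank statistics against
brute-force oracles (1,000 random instances, ≤ 6 conditions × ≤ 20
voxels); permutation type-I error within the exact binomial 99%
interval around α = 0.05 (1,000 null simulations at 100 voxels,
n_perm = 500); full recovery of all 8 planted models with q < 0.05 and
≥ 90% noise-region specificity on the default 18-subject study
(n_perm = 1,000); complexity-type vs general-complexity discrimination
in ≥ 95% of 100 scaled-down runs (8 subjects, 100 voxels); and Storey
FDR calibration at m = 1,000 over 200 replicates. These sizes keep the
whole suite under a minute on a single core while leaving the binomial
tolerances tight enough to detect real miscalibration.

## Known limitations

* No cross-validated distance estimators (crossnobis/LDC); plain
  correlation distance is what this design calls for, but it is biased
  toward the noise floor at low SNR.
* No noise-ceiling estimation or bootstrap confidence intervals on RDM
  correlations; inference is permutation-based only.
* The Storey estimator's small-family fallback (single λ = 0.5) is
  conservative when signals are abundant; with m = 22 regions this is
  the right trade-off, but users with thousands of tests get the
  smoothed estimator automatically.
* Model RDM input is limited to the five built-in families plus
  user-supplied TSV matrices; there is deliberately no model DSL.
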