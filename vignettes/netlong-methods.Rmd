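---
title: "Methods: longitudinal network-based statistics on partial-correlation connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal network-based statistics on partial-correlation connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlong)
```

`netlong` implements a complete analysis chain for longitudinal
resting-state functional-connectivity studies on a fixed set of regions of
interest (ROIs): signal cleaning, partial-correlation connectome
construction, network-level inference against behavior (cross-sectional) and
across sessions (longitudinal, mixed models), behavioral statistics for
pair-bonding assays, and dual regression. This vignette is the package's own
account of the models, conventions and numerical choices; everything stated
here is exercised by the test suite.

## From time series to connectomes

**Cleaning.** The pipeline order is fixed: discard initial volumes (default
5, matching an acquisition of 305 volumes at TR = 2 s of which 300 are
retained), regress out nuisance signals, band-pass filter, and — for
volumetric data — box smoothing. All steps are linear operators, so their
composition is order-stable within each linear family; the order above is
the one the package commits to and tests.

* *Nuisance regressors.* The top five left singular vectors of the centered
  non-gray-matter voxel matrix (`extract_nuisance_eigenvectors()`), plus six
  motion parameters supplied as a table. Regression always includes an
  intercept, so residuals are demeaned — required for the correlations
  downstream. Motion parameters are inputs, not estimates: registration and
  motion correction are out of scope.
* *Band-pass.* The passband 0.01–0.1 Hz is a contract, not a filter recipe;
  the implementation is a zero-phase forward–backward Butterworth of order 5
  (`signal::filtfilt`), the standard choice in resting-state fMRI. Series
  are demeaned before filtering (DC is outside the passband anyway), which
  also suppresses boundary transients of the forward–backward pass. Tests
  pin the contract: gain ≥ 0.9 at 0.05 Hz, ≤ 0.1 at 0.2 Hz, no phase shift.
* *Box smoothing.* Mean over a k³ neighborhood (default k = 3 voxels); at
  array boundaries the window shrinks to in-bounds voxels, so constant
  volumes are preserved exactly (no zero-padding bias).

**Partial correlations.** Edge values are Fisher z-transformed partial
correlations, computed through the inverse covariance:
ρᵢⱼ = −ωᵢⱼ/√(ωᵢᵢωⱼⱼ). This is O(p³) and numerically stable; the equivalent
residual-regression definition (regress ROI i and j on all others, correlate
residuals) is kept as an independent test oracle, with agreement required to
1e−10. With ~300 time points and 16 ROIs the sample estimator is well posed,
so no shrinkage is applied by default; a `ridge` argument exists for p ≈ n
situations. Correlation is scale-invariant, so whether series are
standardised first is immaterial (tested as an invariance).

**Edge indexing.** Edges are the upper triangle in row-major order, with a
canonical ROI list shipped in `roi_set()` (16 social-circuit regions; a
9-region control set), so edge ids are stable across runs and 16 ROIs always
give 120 edges, 9 ROIs 36.

## Network-based inference

Both inference paths follow the network-based statistic (NBS) logic:
edge-wise statistics → fixed suprathreshold graph → connected components →
component *strength* = sum of absolute edge statistics (the "intensity"
definition; an edge-count "extent" alternative was deliberately not added
because strength is what the reference methodology sums) → FWE p-values from
the permutation distribution of the maximum component strength, with the
add-one estimator (1 + #{null ≥ obs})/(1 + B), which can never return zero.
Correlation matrices themselves are never thresholded — the threshold
applies to test statistics only.

### Cross-sectional GLM path (`nbs_glm`)

Per edge, OLS of connectivity on the behavioral covariate (intercept always
included); the statistic is the covariate's t. The default fixed threshold
is T > 1.7 with B = 5000 permutations. Positive and negative associations
are tested as separate one-directional contrasts, each against its own null
(both by default, since either direction can be of interest). Permutation
scheme: the covariate vector is permuted across subjects — exchangeable
under the null of no association; when nuisance covariates are supplied the
Freedman–Lane scheme is used instead (reduced-model residuals are permuted,
nuisance kept in the refit).

### Longitudinal mixed-model path (`nbr_lmm`)

Per edge, a linear mixed model of the Fisher-z value on sex and session
(optionally their interaction) with a subject-level random intercept, fitted
by REML. Term tests are Wald F with *inner–outer* degrees of freedom:
within-subject terms get n_obs − n_subjects − (term df), between-subject
terms n_subjects − (term df) − 1. For the design the package defaults
emulate (90 observations, 32 subjects, 3 sessions) this yields F(2, 56) for
session and F(1, 30) for sex, and post hoc t(56) — the classic layout for
this design. The fixed structure defaults to `~ sex + session`; the
interaction is available (`~ sex * session`) and is tested with the
within-subject rule. No Satterthwaite or Kenward–Roger approximation is
offered: the fixed df rule is part of the method's contract.

The edge statistic entering component strength is a signed z-equivalent,
sign(dominant contrast) × √F. The sign convention for multi-df terms is not
externally standardised; it is documented here and tested for internal
consistency (|z| = √F always; the sign matches the largest-|t| coefficient
of the term block).

**Random structure.** "Random intercept and session" is read as a per-subject
intercept plus per-subject session deviations with diagonal covariance.
`fit_edge_lmm()` attempts this richer structure via `nlme` and falls back to
the random intercept with a warning when it cannot be fitted — with only
three observations per subject the deviation structure is weakly identified,
so the fallback is the practical workhorse. The component-level permutation
test uses the random-intercept model throughout, for both observed and
permuted statistics: the FWE comparison is only exchangeable if both sides
use the same statistic, and a structure that intermittently fails to
converge inside a permutation loop would break that symmetry. The
permutation engine is compiled (RcppArmadillo): the restricted likelihood is
profiled down to the variance ratio λ = τ²/σ², whose normal-equation matrix
A(λ) is shared by all edges, so a λ-grid (log-spaced, −10 to 6, step 0.5)
amortises the decompositions across edges and a golden-section refinement
sharpens each edge's optimum. Agreement with `nlme::lme` is tested at 1e−3
relative on F statistics, and on balanced complete data the session Wald F
must match the classical subject × session repeated-measures decomposition
to 1e−6 relative.

**Restricted permutations.** Exchangeability respects the grouping: for
session and interaction terms, session labels are permuted *within* each
subject (independently per subject, only among that subject's observed
sessions); for the sex term, sex labels are permuted across subjects.
Missing cells stay missing — subjects contribute whatever sessions they
have, by likelihood, with no imputation or casewise deletion.

**Post hocs.** `emm_posthoc()` computes estimated marginal means per session
(model cell means averaged over the other factors with equal weights — on
balanced data these equal arithmetic session means, a tested identity) and
the three pairwise contrasts per edge at the within-subject df, then applies
Benjamini–Hochberg FDR across *all* contrasts of one component (one FDR
family per detected network).

## Behavioral statistics

The partner-preference index is time-with-partner / (time-with-partner +
time-with-stranger); huddling latency is the start (in minutes) of the first
continuous side-to-side contact bout of at least 10 s, missing when none
occurs. `mann_whitney_with_effect()` computes U from rank sums with midranks
and the tie-corrected variance. The effect size is r = |Z|/√N with two
deliberate conventions: Z from the normal approximation **without**
continuity correction, and N = the number of unique subjects contributing
observations rather than the number of sample values (a paired-proportion
comparison of 32 subjects contributes 64 values but N = 32). This pair of
conventions is the only one that reproduces all four published (U, r) pairs
the package's acceptance tests check; the p-value path may optionally apply
the continuity correction. A-posteriori edge–behavior correlations use the
closed-form t = r√(n−2)/√(1−r²) (Pearson, or the same approximation on
Spearman's ρ), two-tailed.

## Dual regression

Stage 1 regresses the group spatial maps onto each time point of a subject's
4D data (multivariate OLS, no intercept), giving one time series per map;
stage 2 regresses each voxel's time course on those series, giving subject
maps. ICA estimation itself is out of scope — group maps are inputs — and
the mixture-model thresholding used upstream of such maps is replaced by a
plain Z ≥ 2.3 cut, stated openly. Variance normalisation of stage-1 series
is off by default (a flag exists). Session differences are tested with
paired t-tests on matched subjects only, with a sign-flip null on the
difference maps and max-|t| FWE correction.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage is testable without data
downloads, with known ground truth. Its defaults are the emulated study
conditions: 32 subjects (16 female), 3 sessions, 16 ROIs, 300 retained
volumes at TR = 2 s, and an explicit (not random) missingness pattern — two
subjects missing session 1, two missing session 3, two session-1 datasets
failing QC — giving 90 of 96 datasets, 26 subjects complete. Latent
structure is specified on the partial-correlation scale: a unit-diagonal
precision matrix with off-diagonal −ρᵢⱼ realises the requested partial
correlations exactly, and rows are i.i.d. multivariate Gaussian draws.

* *Planted session effects* are additive shifts on chosen edges' latent
  partial correlations in chosen sessions.
* *Planted behavior couplings* work through a shared per-subject factor: all
  coupled edges receive one subject-level deviation (SD 0.15 on the
  partial-correlation scale, a moderate individual-differences magnitude),
  and the behavioral value is intercept + slope × mean true Fisher z +
  Gaussian noise. The shared factor is what makes a planted *network*
  coherent — independent per-edge deviations would dilute each edge's
  association with the single behavioral value by ~1/√k and plant k separate
  weak effects rather than one network-level one. In the rare event that a
  large deviation breaks positive definiteness of the induced precision, the
  deviation is shrunk geometrically until valid.
* An optional AR(1) knob adds temporal autocorrelation (band-passed fMRI is
  autocorrelated); it is off by default because the downstream statistics
  operate on cross-sectional correlations of long series.

What the generator does **not** emulate: hemodynamics, scanner noise and
drifts, motion, spatially structured artefacts, inter-regional delay
structure, or heavy-tailed noise. Passing calibration and recovery tests on
these cohorts therefore demonstrates correctness of the statistical
machinery under its own assumptions — Gaussian data with the declared
covariance structure — not robustness to everything real fMRI does.
Effect sizes (shifts, slopes, factor SDs) are free parameters of the
generator, not calibrated to any empirical dataset.

## Calibration and recovery (what the heavy tests do)

The test suite fixes the Monte-Carlo scales as the package's validation
design:

* GLM path type-I error: 200 null cohorts (28 subjects, 120 edges, identity
  latent structure), 500 permutations each, one-directional contrast;
  family-wise rejection fraction must lie in [0.02, 0.08].
* LMM path type-I error: 100 null longitudinal cohorts at the full default
  design (90 datasets with the standard missingness), 500 permutations;
  rejection fraction in [0.02, 0.09].
* Recovery: a planted 9-edge path coupled to behavior (baseline, negative
  slope) and a planted 10-edge ring with a +0.12 session-3 shift, each on a
  10-ROI cohort, must be recovered with edge Jaccard ≥ 0.6 against the
  planted set in ≥ 90% of 50 seeds. On the full 16-ROI grid the same planted
  session network must be *covered* (≥ 80% of planted edges inside the
  detected component) in ≥ 90% of seeds — at edge-level α = 0.05 roughly 5%
  of the ~110 null edges are suprathreshold by construction and many touch
  the component's 10 nodes, so the detected component's edge *set* carries a
  handful of incidental edges in expectation; set-overlap metrics on dense
  grids must account for this, which is why the dense-grid check is coverage
  rather than Jaccard.
* Estimator identities: inverse-covariance vs. residual-regression partial
  correlations (1e−10); union-find components vs. exhaustive reachability on
  1000 random graphs of ≤ 8 nodes (exact); REML engine vs. `nlme` and vs.
  the balanced repeated-measures decomposition; a planted 0.3 session shift
  recovered without bias across 100 simulated edges.

## Numerical choices and degenerate inputs

* Variance-ratio optimisation: λ ∈ e^[−10, 6] covers effectively-zero to
  overwhelming subject variance; boundary fits (λ → 0) are legitimate
  results, not errors. Refinement uses 30 golden-section iterations for
  observed fits, 8 inside permutation loops (permutation maxima tolerate
  ~1e−4 relative error in F; observed statistics get the tight setting).
* Degenerate edges (zero variance, non-positive residual sums) are excluded
  with their indices recorded in the result (`excluded`), never silently.
* Constant columns, rank-deficient designs, non-positive-definite latent
  structures, overlapping masks, and mismatched grids all raise immediate
  errors naming the offender.
* Serialization writes floats with 17 significant digits (TSV/CSV) —
  bit-exact round trips — and JSON at full precision (round trips tested at
  1e−12). Results never embed timestamps, so identical seeds give
  byte-identical summaries.

## Known limitations

* The LMM permutation engine requires the three-level session design it was
  built for; other longitudinal layouts would need the general (`nlme`)
  path.
* The inner–outer df rule is a convention; with heavy imbalance it can be
  liberal relative to Satterthwaite-type approximations.
* Dual regression here is the matrix core plus a simplified voxel-wise
  paired test; it is not a full voxel-wise GLM framework (no TFCE, no
  cluster-forming thresholds).
* The generator's i.i.d. rows understate the effective autocorrelation of
  filtered fMRI; per-edge z noise in synthetic cohorts is therefore somewhat
  smaller than in matched real data at the same number of volumes.
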