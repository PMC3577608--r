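---
title: "Methods: multiclass connectivity-pattern analysis in connsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiclass connectivity-pattern analysis in connsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Schizophrenia aggregates in families, but most healthy first-degree relatives
never develop the illness. Resting-state functional connectivity — the
Pearson correlation between the BOLD time series of pairs of brain regions —
offers a way to separate three kinds of connectivity alteration:

* **state** patterns, present in patients only (expression of the illness),
* **trait** patterns, shared by patients and their healthy siblings
  (candidate endophenotypes of genetic vulnerability),
* **compensatory** patterns, specific to healthy siblings (hypothesized to
  offset genetic risk).

`connsig` implements a three-group (patient / healthy sibling / healthy
control) multiclass pattern analysis that classifies subjects from their
whole-brain connectivity profile and then reads the classifier weights back
in edge space to extract these three signature sets. Because the original
cohort's fMRI data were never deposited, the package ships a synthetic cohort
generator with planted, recoverable effects; all quantitative guarantees in
the test suite are statements about that stated synthetic world, not about
any clinical data set.

# Pipeline

## Temporal preprocessing

The pipeline starts from regional mean time series (regions × volumes); the
spatial steps that produce them (realignment, normalization, smoothing,
parcellation into 116 anatomical regions) are out of scope.

1. **Initial-volume discard.** The first `k` volumes (default 5 for raw
   acquisitions; a 6-minute session at TR = 2 s yields 180 volumes, leaving
   175) are dropped for magnetic-saturation equilibration.
2. **Band-pass filter.** Chebyshev Type I band-pass, 0.01–0.08 Hz. The
   source analysis names only "Chebyshev band-pass"; we fix Type I,
   order 4, 0.5 dB pass-band ripple, and apply the filter forward and
   backward (zero phase). All four choices are exposed as arguments. The
   filter is designed in zero-pole-gain form and run as second-order
   sections with steady-state initial conditions and odd-symmetric edge
   padding; this stays numerically stable at the very low normalized
   cut-off (0.01 Hz at a 0.5 Hz sampling rate), where a single
   transfer-function polynomial of order 8 would be badly conditioned.
3. **Nuisance regression.** Ordinary least squares of each regional series
   on an intercept, the global mean signal, and the six motion parameters
   (translations and rotations only — no derivatives or squares, since only
   those six are named upstream). Residuals become the analysis series.
   The stage order is filter → regress, matching the order stated in the
   source description; to avoid re-introducing out-of-band variance, the
   nuisance regressors are passed through the same band-pass before
   regression. Because filtering is linear this removes filtered nuisance
   content exactly.

A region left with zero variance after filtering (e.g. a constant input) is
flagged; computing a correlation on it is an error naming the region rather
than a silent `NaN`.

## Connectivity features

Pearson correlations between all region pairs give an R × R symmetric
matrix; its upper triangle, vectorized row-major — (1,2), (1,3), …, (1,R),
(2,3), … — is the feature vector. For R = 116 this is E = 6670 features.
The raw correlation is the feature; a Fisher-z option exists but is off by
default, since the method being reproduced feeds correlations directly.

## PCA + one-against-rest linear SVM

Within each training set, features are mean-centered and projected onto the
leading principal components. The retained dimension `d` is not specified by
the source analysis; the default is `n_train − 1`, the maximal rank of the
centered training matrix. This choice is lossless for a linear classifier
(the SVM solution lies in the span of the training data), avoids an
arbitrary variance cutoff, and keeps weight back-projection exact.
Component signs are fixed (largest-magnitude loading entry positive) so the
decomposition is deterministic.

Three linear soft-margin SVMs are trained one-against-rest; prediction is
the class whose machine outputs the largest decision value, with ties going
to the earlier class in the fixed order (patient, sibling, control). The
cost parameter C is likewise unreported upstream; the default is C = 1,
exposed as an argument. The solver is L1-loss dual coordinate descent with
active-set shrinking (the LIBLINEAR algorithm), written in C++ with a
private, fixed-seed coordinate shuffler so that training is a pure function
of its inputs. The bias is realized as an augmented constant feature; at
large C the solver reproduces hard-margin solutions to four decimals, which
the tests check against the one-dimensional closed form `w = 2 / gap`.
Default solver tolerance is 1e-3 (tighter than LIBLINEAR's 0.1); tests that
compare against analytic optima tighten it further.

## Cross-validation and the permutation null

Generalization is estimated by leave-one-out cross-validation. PCA and all
three SVMs are refit on every fold's training subjects only; the held-out
subject never touches the transform. A leakage test asserts that replacing
the held-out subject's features changes nothing in that fold's model.

Significance comes from a label-permutation test: all subject labels are
permuted uniformly, the entire LOOCV is rerun, and the permuted-label
accuracy is recorded; the default is 1,000 permutations. The p-value uses
the add-one estimator `(#{null ≥ observed} + 1) / (n_perm + 1)`, which is
never zero; with the observed accuracy above all 1,000 nulls this gives
p = 1/1001 ≈ 0.000999. One master seed drives a derived seed per
permutation, so results are reproducible and independent of iteration
order. One exact optimization: because PCA is unsupervised, each fold's
projection is identical under every label permutation, so fold projections
are computed once and reused; only the SVMs are retrained per permutation.

## Signatures

Each fold of each one-against-rest classifier yields a weight vector in
that fold's PCA basis. The source description averages weight vectors over
folds and then maps the average back to edge space; but each fold has its
own basis, so averaging raw `d`-dimensional weights across folds is
ill-defined. We therefore back-project each fold's weights through that
fold's own loadings (`V w`, exact for decision values because the columns
of `V` are orthonormal) and average in edge space. When all folds share one
basis the two orders coincide, so this is a strict generalization of the
stated procedure.

Edges are ranked by absolute averaged weight and the top 5% selected per
classifier: `floor(0.05 × 6670) = 333` edges at full scale. (The source
figures report 330; `top_k = 330` reproduces that count, the computed floor
is the default.) Ties at the cut go to the lower edge index.

The mapping from classifiers to signature types is not stated upstream and
is our design decision, configurable via the `mapping` argument:
patient-vs-rest → state (what makes patients unlike everyone),
control-vs-rest → trait (what separates controls from the two genetically
loaded groups, i.e. shared abnormality), sibling-vs-rest → compensatory
(what makes unaffected siblings unlike both). This follows the stated
semantics of each pattern type.

# The synthetic cohort generator

`cohort_config()` + `generate_cohort()` emulate the study's design: three
groups (default 24 patients / 25 siblings / 22 controls, the retained
sample; balanced mode for power studies), R regions × 175 retained volumes
at TR = 2 s. Group structure lives in the target correlation matrix:
a constant-background network (default r = 0.1) plus planted edge lists —
state edges shifted by `delta_r` in patients, trait edges in patients and
siblings, compensatory edges in siblings only. If a perturbed matrix loses
positive definiteness it is repaired by eigenvalue flooring at 1e-6 and
diagonal re-normalization (minimal distortion of the planted shifts,
deterministic), and the repair is flagged.

Subjects are sampled as lag-1 autoregressive Gaussian series initialized at
stationarity, so the cross-sectional correlation equals the target matrix
exactly in expectation; `ar_coefficient = 0` gives an i.i.d. mode for exact
law-of-large-numbers oracles. On top of the neural signal the generator
adds a shared global component (equal loading on every region — exactly the
structure global-mean regression removes, which makes that stage testable)
and six smooth motion-like drift regressors that contaminate the data
linearly and travel with the subject for nuisance regression.

Free parameters the source does not pin down — effect size `delta_r`
(default 0.5), background correlation 0.1, AR coefficient 0.4, global
signal SD 0.5, motion SD 0.3 — were chosen once as plausible for
resting-state BOLD at TR = 2 s: a lag-1 autocorrelation of ~0.4 matches
band-limited BOLD smoothness, and a 0.5 correlation shift is a strong but
not degenerate group effect given the sampling noise of a correlation at
T = 175 (±0.075 SD). They are declared in `cohort_config()` and never tuned
against test outcomes.

What the generator does **not** emulate: voxel-level structure and spatial
preprocessing, hemodynamic response shape, non-Gaussian artifacts, scanner
drift, realistic network topology (the background is exchangeable rather
than modular), or site/demographic confounds. A green test therefore
establishes that the pipeline recovers planted covariance structure under
BOLD-like noise — not that it would achieve any particular accuracy on real
clinical data; the original study's real-data numbers (62.0% LOOCV
accuracy) are out of reach without the undeposited data, and the acceptance
suite instead checks structural identities, null calibration, and
significance/recovery in the scaled synthetic world (R = 30 keeps the
permutation runs on one CPU within minutes; all planted-effect geometry is
preserved).

# Numerical choices and degenerate inputs

* Correlation features are used raw; features are centered by the PCA mean
  only (no unit-variance scaling) since all features share the [-1, 1]
  correlation scale.
* `d` must satisfy `d ≤ min(n_train − 1, p)`; violations are errors, not
  silent truncation.
* The permutation p-value can never be 0 (add-one estimator).
* Zero-variance regions, rank-deficient nuisance designs (the collinear
  column is named), missing cells in input tables (located by row/column),
  unknown class names, and subjects listed without data files are all hard
  errors.
* Tie-breaks are deterministic everywhere: argmax → earlier class in class
  order; edge-rank ties → lower edge index.

# Known limitations

* The SVM solver handles the bias as a regularized augmented feature
  (LIBLINEAR convention); for centered, near-balanced problems this matches
  the unregularized-bias C-SVC closely, and exactly in the hard-margin
  limit checked by the tests, but decision values can differ slightly from
  an SMO-based C-SVC on strongly offset data.
* LOOCV on null data is known to be slightly pessimistic (accuracy a few
  points below 33.3% chance); the null-calibration acceptance band
  [0.28, 0.39] reflects that property of LOOCV itself, not a defect of the
  permutation machinery.
* The per-list `delta_r` is a single signed shift applied uniformly to the
  list's edges; real group differences are heterogeneous in sign and size.
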