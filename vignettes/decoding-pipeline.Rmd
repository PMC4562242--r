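---
title: "Searchlight decoding with permutation-bootstrap group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight decoding with permutation-bootstrap group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decodelight)
```

decodelight implements the complete decoding workflow for event-related
fMRI: least-squares-separate (LSS) trial-wise amplitude estimation, Gaussian
naive Bayes (GNB) classification under leave-one-run-out cross-validation in
regions of interest and spherical searchlights, and nonparametric group
inference by within-run label permutation, bootstrap resampling and
cluster-size correction. A synthetic-data generator emulating a 3-person ×
2-emotion preference paradigm makes every stage testable end to end. This
vignette explains the models, the tunable parameters, and the numerical and
design choices — in particular those the workflow's usual verbal description
leaves open.

## The simulated experiment

The generator reproduces the structure of a rapid event-related design:

* six conditions (`H1, S1, H2, S2, H3, S3`: three fictitious individuals ×
  happy/sad emotional states), six trials per condition per run (36 trials),
  2 s trials, 4–10 s jittered fixation intervals, TR = 1 s, ten runs by
  default;
* behavioral responses drawn per trial (`p_correct = 0.94` by default,
  matching typical task accuracy near 94%; `p_respond = 0.98`). The
  no-preference conditions H3/S3 have no objectively correct answer, so for
  them `correct` is defined as `responded` — one filtering rule ("keep
  correct trials") then implements both the correct-trial filter for
  preference targets and the responded filter for control targets;
* BOLD volumes built voxelwise as baseline + HRF-convolved condition
  responses + cosine drift + motion leakage + AR(1) Gaussian noise.

Each trial of any condition evokes a common response (`common_amplitude`)
across an "active" region; the four preference conditions additionally evoke
condition-specific Gaussian amplitude vectors over that region, scaled by
`pattern_scale` — the effect-size dial. H3 and S3 share a single vector, so
a 2-way H3-vs-S3 decoder must stay at chance by construction: the negative
control every analysis below is checked against.

Jitter is drawn from a continuous uniform distribution on [4, 10] s and
rounded to the TR grid. (The original optimal-sequencing approach to jitter
is deliberately not reproduced; uniform jitter preserves the statistical
structure — overlapping, collinear trial responses — that the LSS stage must
cope with.) Run length is whatever the trials plus initial/final rest
require, rounded up to whole volumes, rather than a fixed 5 minutes.

What the generator does *not* emulate: spatial autocorrelation of noise,
field distortions, physiological noise, or true head-motion image effects
(only the regressor-leak pathway is modeled). Passing tests therefore
demonstrate the *analysis chain* is correct and calibrated, not that it has
been validated against the full complexity of scanner data.

## Trial-wise estimation (LSS)

Each trial's design matrix contains the trial's own regressor (2 s boxcar
convolved with a canonical double-gamma HRF), one regressor collapsing all
other trials, the six motion parameters and a run intercept. The HRF uses
peak shape 6, undershoot shape 16, unit rate scales and undershoot ratio
1/6, sampled at TR/16 and normalized to unit peak so amplitudes are in
signal units; all of this is exposed through `hrf_double_gamma()`.
Convolution happens on the 16× oversampled grid and is decimated at volume
times. Whether run intercepts or drift terms belong in the trial models is
genuinely open in the usual description of this estimator; we default to an
intercept per run, no drift regressors (high-pass filtering is a
preprocessing concern), and expose both (`intercept`, `drift`).

Implementation note: the per-trial fits are computed from one per-run
cross-product decomposition (Gram matrix of all trial regressors plus
nuisance, recombined per trial), which is algebraically identical to solving
each trial's normal equations separately; the test suite verifies agreement
with a naive per-trial solver at 1e-10.

A property worth knowing: per-trial LSS estimates are *exactly* unbiased on
noise-free data only when the data lie in each trial model's span — e.g.
uniform trial amplitudes, or mutually orthogonal regressors that are also
orthogonal to the nuisance block. With overlapping responses and
heterogeneous amplitudes the collapsed other-trials regressor absorbs the
rest only approximately; that residual interference is precisely the
trade-off this estimator makes to tame collinearity in fast designs.

## Decoding

`crossvalidate_loro()` implements the fold loop. Choices the verbal recipe
leaves open, and what we do:

* **Eligibility.** Correct trials only (see above for how the control
  conditions fold into this rule). Filtering applies to training and test.
* **Balancing.** The training partition of each fold is downsampled, per
  class, to the minimum class count with a seeded draw; the test partition
  is never balanced — discarding test trials would only throw away
  information, and the accuracy metric pools counts over folds. When counts
  are already equal, everything is kept and no randomness is consumed (this
  keep-all rule is what makes the compiled and reference engines, and the
  ROI and searchlight paths, exactly comparable on balanced data).
* **Normalization.** Each sample (trial) is z-scored across its voxels with
  the population (divide-by-n) SD; the sample-SD alternative differs only by
  a constant row factor, which GNB ranking ignores. In searchlights the
  z-scoring uses the sphere's own voxel subset, since each sphere is an
  independent decoding problem.
* **Feature selection** (ROI analyses): one-way ANOVA F per voxel on the
  balanced, normalized training samples; top-k voxels, ties broken by
  ascending index. k = 123 by default, matching the searchlight sphere size;
  123/200/300/400 are the conventional settings.
* **GNB.** Per-class, per-feature means and population variances
  (non-pooled), floored at 1e-9 × the mean feature variance to keep
  log-densities finite on near-constant features; uniform class priors
  (training is balanced by construction); prediction is the arg max of
  log-prior plus summed Gaussian log-densities, ties to the first class in
  canonical label order. Everything is deterministic.

Confusion matrices are accumulated as counts (rows = actual), and
row-scaled to percentages so each row sums to 100. A result is
"diagonal-dominant" when every row's diagonal entry strictly exceeds its
off-diagonal entries — the criterion for claiming that *all* classes, not
just some, are discriminated.

## Searchlight

`sphere_offsets(r)` enumerates integer offsets with squared norm ≤ r²; at
the default radius 3 (isotropic voxel units — the intended voxel grid is
near-isotropic, and no anisotropy correction is applied) the sphere holds
123 voxels. Spheres truncated by the mask are used as-is, with the
per-center voxel count emitted for transparency; centers with fewer than two
usable voxels are left undefined. The compiled engine evaluates, per
center, the full leave-one-run-out GNB decode for the true labels *and* all
permuted label sets in one pass, sharing the per-center z-normalized data
(which do not depend on labels). Balancing draws are keyed on (seed,
center, fold, label set) with a counter-based generator, so results are
independent of the order or partitioning of centers. A pure-R engine
(`engine = "R"`) mirrors the computation for auditability, and the test
suite checks exact agreement.

## Group inference

For each subject, condition labels of the eligible trials are permuted
within runs (`n_perm` times; 100 in a full analysis, 10 in the scaled-down
test settings) and the whole decoding analysis is repeated, yielding chance
accuracies (ROI) or chance maps (searchlight). The bootstrap then draws,
with replacement, one chance value per subject and averages across subjects
(`n_boot` times; 10^5 full scale, 10^3 scaled down). Empirical p-values use
the add-one estimator p = (1 + #{null ≥ observed}) / (1 + N), which cannot
return zero.

Searchlight maps are thresholded voxelwise at p < 0.001. Cluster-size
inference needs supra-threshold clusters *in the chance maps* too. Here a
subtle numerical point arises: at N = 10^3 bootstrap draws, a chance map
compared against a null set that includes itself can never reach
p < 0.001 — its own value always counts once, so its p is at least
2/(N+1) — and the cluster-size null would be empty by construction, which
at full scale (N = 10^5) it is not. We therefore threshold each chance map
with the same add-one formula the observed map uses, treating the tested
map as the "+1" pseudo-draw: p_j(v) = (1 + #{k ≠ j: null_k(v) ≥
null_j(v)}) / (1 + N). This is the identical estimator, keeps the chance
and observed thresholding consistent, and yields a usable, calibrated
cluster-size null at reduced resampling counts.

Cluster formation uses 26-connectivity by default (6-connectivity
available). Observed clusters receive add-one p-values against the pooled
chance cluster sizes, and Benjamini–Hochberg FDR at q < 0.05 is applied
across the observed clusters. (An alternative reading of this scheme applies
FDR over the chance clusters to derive a size cutoff; we implement the
observed-cluster form, which states its assumptions — each observed cluster
is one hypothesis — most directly and is what `cluster_pvalues_fdr()`
computes.) If the chance cluster distribution is empty — possible in
principle at tiny resampling settings — every observed cluster is assigned
the minimum attainable p given the number of chance maps and a warning is
raised rather than silently declaring significance. Each significant
cluster is reported with its size, peak-accuracy coordinate and
cluster-level confusion matrix: scaled center matrices averaged within the
cluster per subject, then across subjects.

Since all simulated subjects share one grid, group inference operates
directly on the subject maps; spatial normalization of real data is outside
this package's scope, and cluster sizes are reported in grid voxels.

## Calibration and power settings

The test suite validates the chain at a reduced problem size chosen to keep
a full run in minutes on one CPU: 6 subjects, 4 runs, a 12×12×12 volume
with a radius-4 active region (257 voxels), 10 permutations and 10^3
bootstrap draws, 20 replicate datasets for the null calibration. On null
data (pattern_scale = 0) the group 4-way accuracy stays within
[0.22, 0.28], the ROI test rejects at most 25% of replicates at p < 0.05,
and at least 80% of replicates yield no FDR-significant cluster. Exact
error control is asymptotic in the resampling counts, so mild
anti-conservatism of the cluster stage at these reduced settings is
expected and is why the bounds are stated as they are.

The power analysis fixes `pattern_scale = 0.06`, calibrated once so that
within-subject 4-way accuracy lands near 50% (the 40–60% band) under the
default noise model (σ = 1, AR(1) 0.3, drift 0.5, motion leak 0.1) — weak
enough to be a realistic effect, strong enough for a 6-subject group test.
At that effect size the searchlight recovers at least one FDR-significant
cluster overlapping the true region with a diagonal-dominant cluster
confusion matrix, while the H3-vs-S3 control analysis on the same data
yields none.

## Known limitations

* No prewhitening or autocorrelation modeling in the GLM (point estimates
  only feed the classifier, so this mirrors standard practice).
* The noise model is spatially independent; real BOLD noise is smooth, so
  real-data cluster nulls are wider than the simulated ones.
* Only GNB is provided; the architecture accepts any per-sphere decoder in
  the reference engine, but the compiled fast path is GNB-specific.
* Cluster peak coordinates are voxel indices on the input grid; mapping to
  a template space is the caller's concern.
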