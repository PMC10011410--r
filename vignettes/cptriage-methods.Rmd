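---
title: "Methods: morphological-profile triage of cellular injury compounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphological-profile triage of cellular injury compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptriage)
```

# Scope and model

`cptriage` analyzes well-level morphological profiles from concentration-
response (qHTS) cell-painting screens, with the goal of flagging compounds
whose bioactivity is driven by cellular injury rather than a specific
mechanism. The pipeline assumes:

* profiles are a rectangular wells × features matrix with plate, compound,
  concentration (µM), replicate, role and cell-count metadata;
* each 384-well plate carries its own vehicle (DMSO) wells — the reference
  population for both normalization and the activity null;
* compounds are tested at a 2-fold dose series (0.625–20 µM by default) with
  one well per dose per plate across replicate plates.

Image acquisition and segmentation are out of scope: the package consumes
feature tables, not images.

## Normalization

Robust z-scores are computed per plate and feature against vehicle wells,
`z = (x − median) / (1.4826·MAD)`; the 1.4826 factor makes the MAD a
consistent estimator of a Gaussian SD, so vehicle wells have median 0 and
robust SD 1 by construction. Features with zero vehicle MAD on any plate are
dropped and reported — they carry no usable scale. The reference population
is vehicle *wells*: per-object (single-cell) normalization is outside the
data model.

Redundant features are removed greedily: while any pair exceeds the
correlation threshold (default 0.9, the common morphological-profiling
convention), the worst pair is located and the member with the larger mean
absolute correlation to the remaining features is dropped, ties broken by
dropping the lexicographically later name. The procedure is deterministic
and idempotent, and the retained set provably has no pair above threshold.
Whether feature reduction precedes activity scoring is ambiguous in the
field; the package defaults to scoring on all normalized features and
clustering/embedding on the reduced set (both configurable).

## Activity score

For each compound × concentration, replicate wells are stacked with all
vehicle wells; PCA is run on the stacked matrix and the smallest prefix of
components explaining ≥ 90% of variance is kept. Group covariances in PC
space are pooled with sample-size weights,
`Σ = (n_t Σ_t + n_c Σ_c)/(n_t + n_c)`, and the score is the Mahalanobis
distance between the group centroids. The PCA convention is **scaled,
uncentered** (`prcomp(center = FALSE, scale. = TRUE)`): profiles are already
vehicle-centered by robust z-scoring, so omitting centering preserves the
vehicle origin; this matches the convention used for the package's PCA
embeddings and is configurable. When the pooled covariance is numerically
singular (few replicates against many components) a ridge of
`1e-6 × mean(diag Σ)` is added and flagged in the output.

The null distribution is built from the vehicle wells themselves: a seeded
shuffle partitions them into pseudo-treatment groups of the replicate count
(default 4), each scored against the remaining vehicles. Because a group
plus the rest is always the full vehicle set, the PCA is shared across
groups — numerically identical to scoring each group independently, which a
test verifies. The cutoff is `mean + 3·SD` of the null distances, and a
score exactly at the cutoff is *inactive* (strict inequality).

## Phenotype clustering and matching

Active treatments (replicate-averaged profiles over the reduced feature set)
are clustered with `1 − Pearson r` distances under Ward's
minimum-increase-of-sum-of-squares criterion. The Lance–Williams update is
applied to squared distances (`ward.D2`), the standard reading of Ward on
non-Euclidean dissimilarities; the unsquared variant (`ward.D`) is
available. k = 9 by default — cluster count is a judgment call in this
field, not an optimized quantity — and inactive treatments are excluded:
clustering noise profiles would be meaningless, and trajectories display
them as unlabeled.

Cluster phenotypes are feature-wise member means. External profiles are
matched by Pearson correlation over the feature intersection (profiles from
historical datasets rarely share the full feature set). The HC/NC call
against a target cluster (by convention the gross-injury cluster, the last
one) uses thresholds hc = 0.5 and nc = 0.2; these are *not* anchored in any
reference analysis and are therefore mandatory-explicit in reports.

Dendrogram entanglement between two clusterings over the same treatments is
`Σ|r1 − r2|^L` over leaf ranks, normalized by the reversed-order worst case,
with L = 1.5 (the customary exponent; the value used by the reference
analysis is not stated). Leaf orders are the trees' natural merge orders; no
untangling search is applied, so reported entanglement is an upper bound on
the optimally-untangled value.

## Cell-health summarization

Live-cell traces (0–60 h, every 4 h) are corrected per plate/metric/time by
subtracting the mean of reagent-free wells (cellular autofluorescence);
negative corrected values are clipped to zero and counted. AUCs integrate
each metric over *time* per concentration — the natural reading for curves
acquired on a time grid; per-concentration aggregation of the time-AUCs is
available separately. Compounds on an exclusion list (e.g. autofluorescent
interferers) stay in the output tables flagged, but are meant to be omitted
from aggregates.

Glutathione luminescence is converted to µM through an unweighted OLS
standard curve fitted on background-corrected triplicate 10-point standards
(6.4 µM → 13 nM, 2-fold). The kit chemistry implies `GSH = total − 2·GSSG`
(each GSSG carries two GSH equivalents). Flags follow the reporting rules:
`outlier_gssg` when GSSG exceeds 200% of vehicle, `gsh_negative` (ratio
withheld) when computed GSH < 0, and `undefined_high` when GSSG is zero to
curve precision with GSH > 0. Percent-of-vehicle scales use the plate's
vehicle wells — the natural reference, though not stated explicitly in the
reporting convention.

# The synthetic generator: what it emulates, and what it does not

`generate_screen()` emits the stated screening world: 16 × 24 plates with
116 vehicle wells (default) and four positive-control compounds at six
doses, compounds at six 2-fold doses on four replicate plates, a few hundred
features in correlated blocks, nine planted phenotype directions, Hill-shaped
dose response, and Poisson cell counts with log-mean
`log(baseline) + coupling·m(c)` (coupling negative: stronger phenotype,
fewer cells).

Key numerical choices, and why:

* **Effect parameterization.** A treatment well is
  `baseline + m(c)·sqrt(p)·s + noise` with `s` a unit-norm signature over
  `p` features, i.e. `m` is the **per-feature RMS effect in units of the
  feature noise SD**. With a fixed total-norm parameterization, statements
  like "effect three times the noise" would silently weaken as features are
  added (per-feature SNR `3/sqrt(p)` is undetectable by any method at
  p ≈ 300); per-feature units make the SNR feature-count-invariant, which is
  what every recovery statement in the test suite assumes. Default
  `effect_max = 3`, `noise_sd = 1`.
* **Correlated blocks.** Features come in blocks (size 5) sharing a latent
  factor at r = 0.95, and signatures are drawn at the *block* level and
  expanded so block-mates respond together — redundant features are
  redundant because they measure the same thing, signal included. This gives
  redundancy reduction real work (typically ~1 retained feature per block).
  Block-level directions are random orthonormal (QR of a Gaussian matrix),
  satisfying the ≤ 0.3 pairwise-cosine bound of `generate_signatures()` for
  any k up to the block count. DMSO-well covariance structure is this
  package's choice; no reference measurement constrains it.
* **Ground-truth activity flag.** `true_active` is `m(c) ≥ 1.5·noise_sd` —
  half the reference SNR of 3, since a Hill curve only approaches its
  asymptote. Empirically, detection at the default scale saturates well
  below this value.
* **EC50s** are jittered 2-fold around the configured value (default
  2.5 µM, the center of the dose range) per compound; **plate effects** are
  additive per-plate feature offsets (SD 0.25), removed by per-plate
  normalization; **cell counts** are Poisson around 1500 cells/well.
* **Time courses**: logistic confluence growth (rate damped by `1 + m`),
  power-law rises of caspase/membrane/overlap object counts with effect, an
  additive fluorescence background of 20 counts measured directly by
  reagent-free wells.
* **Glutathione**: vehicle wells at 4 µM total / 0.25 µM GSSG (GSSG ≈ 6% of
  total, a realistic oxidation state); electrophile-class compounds deplete
  total by up to 85% and raise GSSG up to 3.5-fold with dose; luminescence
  is `gain·conc + background` with 1% relative noise.

What the generator does **not** emulate: spatial plate artifacts (edge
effects, row/column gradients), per-object heterogeneity, feature
distributions with heavy tails, compound carry-over, or any image-level
interference. A green recovery test therefore establishes that the
*algorithms* recover the structure they claim to recover under the stated
noise model — not that the pipeline is robust to every real-plate pathology.

# Tolerances, degenerate inputs and tie-breaks

* Vehicle medians/MADs after normalization are exact to 1e-9; CSV
  round-trips are exact on metadata and within 1e-12 relative on values.
* Oracle equivalence of the Mahalanobis score is asserted to 1e-8 against a
  brute-force eigendecomposition implementation.
* Zero-variance features (normalization, PCA scaling, correlation) and
  zero-variance profiles fail fast with the offender named; missing values
  are rejected at ingestion rather than imputed.
* Glutathione recovery under 1% luminescence noise is asserted as **mean**
  absolute relative error ≤ 3% per quantity: at the smallest planted GSSG
  (0.25 µM, the bottom of the calibration range) the OLS intercept
  uncertainty alone propagates ~2% relative error, so a per-measurement
  max bound would fail occasionally by construction, independent of
  implementation quality. The per-row max is additionally bounded at 5% in
  the unit tests.
* Clustering ties follow `stats::hclust`'s deterministic merge order;
  redundancy-reduction ties drop the lexicographically later feature name.
* All randomness (generator sub-streams, null partitions) derives from
  explicit seeds; identical configuration is byte-identical output, which
  the pipeline tests assert via file hashes.

# Known limitations

* The activity null uses pseudo-groups of vehicle wells; with few vehicle
  wells the null SD is estimated from few distances and the cutoff is
  correspondingly noisy (a minimum of 8 null distances is enforced).
* Scoring granularity defaults to per compound × concentration (the reading
  behind trajectory plots); a per-compound pooled score is available via
  `score_screen(granularity = "compound")` but pools dose-dependent effects
  into one distance, which blurs weak top-dose-only actives.
* No multiple-testing correction is applied across compounds, matching the
  reference practice for 3-SD activity calls.
* Entanglement is reported without untangling optimization and is not
  comparable across different leaf-ordering heuristics.
* Row/column uniformity correction for luminescence plates is applied only
  when uniformity plates are supplied; otherwise a logged message is the
  only trace.
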