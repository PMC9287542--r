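---
title: "Assessing and ranking segmentation algorithms with segrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and ranking segmentation algorithms with segrank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrank)
```

## The assessment problem

A multi-task segmentation benchmark compares `N_A` algorithms on a set of
tasks (data sets), each with one to three target structures (ROIs) and its
own number of test cases `N_i`. Case counts and task difficulty vary so much
between tasks that averaging raw metric values across tasks would silently
weight tasks by sample size and difficulty. `segrank` instead implements a
rank-then-aggregate pipeline built on within-task paired statistics, which
needs no cross-task score normalisation at all. Its two inputs are a
per-case metric table (team, task, case, ROI, metric, value) and a task
configuration carrying the ROI label map and the NSD tolerance per task.

## Metrics

**DSC.** The Dice similarity coefficient `2|P∩G|/(|P|+|G|)` on 3D voxel
sets. It is volume-dominated: single-voxel boundary errors barely move it on
large organs, but swing it heavily on small lesions.

**NSD.** The normalized surface dice compares boundaries, not volumes: a
boundary voxel of one mask counts as "acceptable" when it lies within a
tolerance `τ` (mm) of the other mask's boundary, and the NSD is the fraction
of acceptable boundary voxels pooled over both directions. The tolerance has
units of millimetres and encodes how much boundary error a clinician would
accept for that task; the packaged ten-task configuration uses task-level
tolerances from 1 mm (hippocampus, a small precise structure) to 7 mm
(liver, a large organ with ambiguous boundaries). Because it saturates once
errors drop below `τ`, NSD complements DSC rather than duplicating it.

Two representation choices matter and are deliberate:

- *Surfaces are boundary voxel centres* under 6-connectivity (a mask voxel
  with at least one face-neighbour outside the mask; the grid edge counts as
  outside). An alternative found in the literature weights surface elements
  by face area; the voxel-centre variant was chosen because it admits an
  exact brute-force oracle (all pairwise distances) against which the
  implementation is verified to the last bit, at isotropic and anisotropic
  spacing.
- *Distances are compared squared.* The implementation computes an exact
  anisotropic squared Euclidean distance transform (a separable
  lower-envelope-of-parabolas algorithm, implemented in C++ with float64
  accumulation) and compares `d² ≤ τ²`. Avoiding the square root means the
  tolerance comparison involves no rounding at all for rational spacings, so
  the distance-transform route and the brute-force route agree exactly even
  for boundary voxels lying precisely at the tolerance.

**The undefined-metric rule.** When both masks (or both boundaries) are
empty, both metrics are 0/0. Following the benchmark protocol, such values
are set to 0. An ROI present in the ground truth but completely missed by a
prediction also scores 0 in both metrics. A *geometry* mismatch (different
grid or spacing), by contrast, is always an error and never a silent 0 —
a silently zeroed case would corrupt every downstream rank.

## Significance ranking

For each (task, ROI, metric) the pipeline:

1. takes the paired per-case values of every team;
2. runs a one-sided Wilcoxon signed-rank test for every ordered team pair
   (does `a` tend to exceed `b`?);
3. scores each team by the number of competitors it beats at the
   per-comparison level `α = 0.05`, deliberately *not* adjusted for
   multiplicity (the score is descriptive, not inferential — adjusting would
   only make every score smaller without changing the ordering logic);
4. converts scores to ranks, rank 1 for the highest score, tied scores
   sharing the mean of the positions they occupy (so fractional shared
   ranks are possible).

The test is one-sided because the score counts algorithms "performing
significantly worse" — a directional claim. A two-sided variant and a Pratt
treatment of zero differences are available behind arguments, but the
defaults are: zeros discarded before ranking (the classic convention, and
the one under which the exact distribution is available), exact null
distribution when the number of non-zero differences is ≤ 25 and their
absolute values are untied, and otherwise a mid-rank normal approximation
with tie correction and continuity correction. With all differences zero
there is no evidence either way and p = 1. The exact branch is verified in
the test suite against full 2^n sign enumeration (n ≤ 12, tolerance 1e-12)
and both branches against `stats::wilcox.test`.

**Aggregation.** Ranks are aggregated hierarchically: the per-ROI rank is
the arithmetic mean of the DSC-rank and the NSD-rank (the protocol defines
scores per metric but not their fusion; the mean mirrors the documented
per-ROI → per-task averaging and keeps both metrics equally weighted); the
per-task rank is the mean of per-ROI ranks; the phase score is the mean of
per-task ranks, and final ranks are assigned ascending in phase score with
the same mid-rank tie rule. An alternative scheme (`scheme = "per_roi"`)
averages over all (task, ROI) ranks directly — it is provided for
sensitivity analysis but over-weights multi-ROI tasks, which is why
per-task averaging is the default.

Note that per-task ranks are *means of ranks* (e.g. 1.375), not re-ranked
integers; only phase-level final ranks are re-ranked. This preserves the
rank-sum invariant `Σ ranks = N_A(N_A+1)/2` at every level of the
hierarchy, which the test suite asserts on randomly simulated tables.

## Bootstrap stability

Rankings derived from small test sets can be fragile. The stability module
resamples test cases with replacement *within each task* — the same
resampled case multiset applied to every team, preserving pairing and block
completeness — and re-runs the entire pipeline per bootstrap sample
(default 1000 samples, the protocol value). Agreement between each
bootstrap ranking and the original is measured per task with Kendall's τ-b
(the tie-corrected variant, since shared ranks are common); a fully tied
ranking makes τ undefined and is recorded as a flagged missing value,
excluded from summaries rather than coerced to a number. Summaries are the
median and IQR of τ per task, with quartiles by linear interpolation
(type 7) so printed values are reproducible across implementations, plus
rank-frequency tables (mid-ranks are multiples of 0.5 and are kept at that
resolution).

Reproducibility: the bootstrap is a pure function of (table, n_samples,
seed). Resample indices for sample *s* of task *t* are drawn from a
substream seeded by `seed + s + (t-1)·n_samples`, so individual samples are
order-independent and could be evaluated in parallel with identical
results; reports serialize byte-identically across reruns.

## Volume I/O conventions

NIfTI volumes are reoriented to the closest right-anterior-superior frame
by the dominant direction cosine per axis — a pure permutation plus flips,
never interpolation, so per-label voxel counts are preserved exactly.
Spacing is derived from the affine's column norms. Voxel values within
1e-6 of an integer are rounded; anything else is rejected as a non-label
map (guarding against lossy-compressed or interpolated label volumes).
A missing or degenerate affine is an orientation error. Robust min-max
intensity scaling (clip at percentiles, map to [0, 1]) is provided for
non-quantitative modalities; the protocol source does not state the
percentiles it used, so they are arguments with defaults (0.5, 99.5) —
values a practitioner would recognise as "robust" while clipping only
gross outliers.

## The synthetic module

The generator exists so that every pipeline stage is testable without any
benchmark data, at three levels of abstraction:

- `generate_phantom_gt()`: one random non-overlapping ellipsoid per ROI.
- `perturb_prediction()`: per-ROI degradation — total miss with probability
  `miss_prob`, translation, Euclidean dilation/erosion (via the same
  distance transform as the NSD), and random boundary flips.
- `simulate_metric_table()`: skips volumes entirely and draws per-case
  metric values from team-specific Beta distributions parameterised by
  (mean, sd), the sd capped just inside the feasibility bound
  `sd² < mean(1-mean)`. The true quality ordering is then the descending
  order of means, giving ranking tests a known ground truth.

What the phantoms *emulate* is the statistical structure the assessment
consumes: label overlaps, surfaces, paired per-case variation, graded team
quality. What they do *not* emulate is everything else about real data —
anatomical shape, intensity distributions, annotation ambiguity, inter-case
difficulty correlation (phantom cases are i.i.d., real cases are not), or
realistic per-task difficulty profiles. Passing tests therefore demonstrate
that the *assessment machinery* is correct and stable, not that any
particular algorithm or task behaves like its real-world counterpart.

Beta-simulated values are drawn independently per (case, ROI, metric); real
DSC and NSD values for the same case are strongly correlated. This makes
the simulation slightly *harder* on rank agreement between metrics than
reality, which is the conservative direction for validating aggregation.

## Problem sizes and defaults used in validation

The shipped tests and `scripts/acceptance.R` use sizes chosen to make every
check exhaustive or statistically decisive while staying quick: random mask
pairs up to 16³ voxels at spacings (1,1,1) and (1,1,2) mm (200 pairs,
tolerances 0–2 mm) for the metric oracles; n ≤ 12 for sign-enumeration
agreement; 50 random cohorts for rank invariants; five teams with Beta
means 0.9–0.5 (sd 0.05), 100 cases and 100 replicates for order recovery;
200 bootstrap samples for the stability limits. The dominance constructions
use n ≥ 6 cases per task because the one-sided exact p-value of a strict
sweep is `2^-n`, which first drops below α = 0.05 at n = 5; n = 6 leaves
a margin so that case resampling cannot lift it above α.

## Known limitations

- The NSD uses voxel-centre surfaces; values differ slightly from
  area-weighted implementations, most visibly at coarse, strongly
  anisotropic voxels. The variant in use is stated here and in the
  function documentation.
- The complete-block requirement is strict by design: a team missing one
  case fails evaluation unless `allow_missing = TRUE` explicitly substitutes
  the undefined-rule 0 (logged loudly).
- No mixed-model or other model-based ranking is offered; the two
  aggregation schemes above are the scope.
- Phantom cohorts do not calibrate per-task difficulty to any real
  benchmark; they are validation instruments, not surrogates for real data.
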