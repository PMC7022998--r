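---
title: "Geometric modelling of training adaptation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric modelling of training adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trainadapt)
```

## The monitoring pipeline

`trainadapt` models whether an athlete's weekly balance of training load and
recovery is producing performance improvement. The raw material is a
season of monitoring streams per athlete: a training log (one row per
session with CR-10 RPE, duration, distance), twice-weekly wellness
questionnaires on 7-point Likert scales, fortnightly mood-profile scores,
and competition results.

From the training log we derive the standard internal-load metrics:

* **session-RPE** = RPE × duration (AU), summed or averaged per week;
* **training monotony** = weekly mean daily load / SD of daily load, over
  the 7 days of the week with rest days counted as 0 AU;
* **training strain** = weekly total load × monotony;
* **ACWR** = week *w*'s load divided by the rolling mean of weeks
  *w−3..w* (undefined before week 4).

Performance is expressed as the percentage of personal best time,
%PBT = (PB/t)²·100, using the personal best held at season start throughout,
so every competition is compared against the same reference. The best
weekly %PBT is dichotomised at 100% into the adaptation label ±1.

### Conventions where the field leaves a choice

* **Monotony SD.** The daily-load SD is the *sample* SD (n−1). The
  literature rarely states the denominator; the choice is exposed as
  `sd_type` and is a uniform scale factor on monotony and strain.
* **ACWR window.** The chronic window *w−3..w* includes the acute week
  (`chronic_window = "inclusive"`, the rolling-average calculation whose
  worked value for weekly sums 1000, 1000, 1000, 2000 is 2000/1250 = 1.6);
  `"exclusive"` drops it. Note that in parts of the ACWR literature the
  *inclusive* window is called "coupled" — the package names the options by
  what they do rather than adopting either label.
* **%PBT = 100 exactly** counts as maladaptation: improvement means
  strictly beating the personal best.
* **Total mood disturbance** is the sum of the five negative dimensions
  minus vigour with no +100 offset; the offset is a monotone shift that
  cannot affect rank-based statistics.
* **Weeks start Monday**; records aggregate by calendar week inside the
  study window. A week with no wellness entries has missing recovery; a
  week with no sessions has zero load and undefined monotony-derived
  metrics.
* **Quartile banding** (`assign_quartiles`) uses competition-style minimum
  ranks with `floor((r−1)·4/n)+1`. This is the unique convention that
  reproduces all 65 quartile cells of the 13-swimmer reference
  characteristics table bundled as `reference_cohort()`, including the
  four tied 15-year-olds in age quartile 1.
* **Inclusion prerequisites** are strict inequalities: response rate
  > 80% in *every* questionnaire, > 75% of sessions recorded, at least one
  %PBT above and one below 100, and complete (x, y) data for every week
  carrying a %PBT value. The completeness check depends on which indicator
  combination is modelled, so `apply_prerequisites()` takes the
  combination id.

## The geometric classifier

For a chosen indicator combination (1: distance/session-RPE,
2: session-RPE/recovery, 3: strain/recovery, 4: monotony/recovery,
5: distance/ACWR), weekly values are normalized by their season maximum so
that all points live in the unit square with maximum exactly 1 on each
axis. Only labelled (competition) weeks enter the geometry.

1. **Clustering.** Each label class is clustered with average-linkage
   agglomerative clustering under three dissimilarities: Bray-Curtis,
   Chebyshev, and the ½-normalized squared Euclidean distance
   ½‖(u−ū)−(v−v̄)‖²/(‖u−ū‖²+‖v−v̄‖²), each vector centred by its own
   component mean. The cluster count per class is chosen in
   2..min(n−1, k_max) by maximizing the Calinski-Harabasz variance-ratio
   criterion, evaluated in Euclidean coordinates (the criterion is
   variance-based, so it is computed in the embedding space regardless of
   the clustering dissimilarity); classes with fewer than 3 points keep
   one cluster, as the criterion is undefined there. `k_max` defaults
   to 4, matched to the 4–8 labelled weeks a season provides.
2. **Metric selection.** The three solutions compete and the one with the
   fewest total patterns wins; ties break by the higher criterion score,
   then by the fixed metric order. This is the model's parsimony pressure.
3. **Convexification.** Each cluster becomes its convex hull. Degenerate
   clusters — singletons, pairs, collinear sets — are buffered by a disk or
   capsule of radius δ (default 0.02) so that every pattern has interior.
4. **Domain map.** On a grid (default 256² cells) every cell centre takes
   the label of the pattern minimizing Euclidean point-to-hull distance;
   a cell covered by overlapping hulls of both labels goes to the hull
   with the nearest centroid. Cells where the two class distance fields
   differ by at most ε (default 0.01) form a neutral separating layer —
   the thin buffer that disconnects the domains of influence and keeps the
   area integration stable at the boundary. The region boundary is
   extracted as the zero contour of the signed distance difference.

Area fractions are computed by cell counting, so
adaptation + maladaptation + neutral = 1 exactly, and

> **GAPI = adaptation area / maladaptation area.**

Goodness of fit classifies each labelled week by the same grid (points in
the neutral layer resolve to the nearest labelled region) and reports
round-half-up integer percent, matching the integer format in which such
tables are conventionally reported (7/8 → 88, 5/8 → 63). A mean
cross-entropy diagnostic of the hard predictions is reported alongside,
with confidences clamped at 1e−3 so the value stays finite.

### Numerical choices

* `grid_resolution` 256 (minimum 32). Doubling the resolution moves each
  area fraction by less than 2/resolution; the validation studies below
  use 128 and 64 where many maps are fitted.
* Exact distance ties between the classes (measure zero off the grid) fall
  into the neutral layer; within overlapping hulls the nearest-centroid
  rule decides deterministically.
* The construction is deterministic and invariant to the input order of
  points; a brute-force nearest-hull scan over all cells reproduces the
  region map exactly in the test suite.

## Jittering and the ensemble

Seasons provide 4–8 labelled weeks, far too few for a flexible classifier,
so the model is refitted on `replicates` (default 50) noise-augmented
copies: independent Gaussian noise with SD = `noise_level` (default 0.10)
× the sample SD of each raw series is added to x, y *and* z before
normalization and binarization — labels of weeks whose %PBT sits near 100
may flip between replicates, which is intended: such weeks genuinely are
uncertain. A multiplicative variant is available. Replicate *r* draws from
a stream derived deterministically from the master seed, so runs
reproduce bit for bit. "Simple averaging" means arithmetic means of the
scalar outputs (GAPI, goodness of fit) plus a per-cell modal label map for
visualization — averaging boundaries directly is ill-defined. Replicates
whose perturbed labels collapse to one class are excluded from the means
with a warning. At `noise_level = 0` all members are provably identical,
so the model is fitted once and replicated.

## Association with performance

Per-athlete ensemble GAPI values are related to the best %PBT and to its
quartile band with two nonparametric statistics: Spearman's ρ (average
ranks for ties; p exact by full enumeration of rank permutations for
n ≤ 9, t-approximation above) and Blomqvist's β (quadrant counts around
the two sample medians, observations on a median dropped — with 13
athletes at least one observation per variable is dropped; exact binomial
p). Two-sided p-values throughout. Holm correction is applied within each
(test, outcome) family across the five combinations, i.e. family size 5;
the family definition is a reporting choice and is echoed in the output.
Report columns round statistics and p-values to two decimals.

## The synthetic cohort

No athlete series are distributed with the package, so every stage is
validated against a generator with known ground truth. A simulated season
emulates:

* 26 weeks, about 6 sessions per week filling fixed-length pool slots;
* periodized **volume blocks** (a lognormal weekly factor, sdlog 0.35,
  about a threefold overload-to-taper range) and independent
  **intensity blocks** (a lognormal weekly factor scaling RPE, sdlog
  0.35). Matching the two relative variations keeps either normalized
  axis from dominating the unit square. Because pool time is scheduled,
  duration is roughly constant and internal load tracks intensity rather
  than distance — this is what makes the distance/session-RPE plane
  informative at all;
* twice-weekly wellness entries whose global recovery falls with
  normalized weekly strain; fortnightly mood profiles with fatigue tied
  to strain;
* competitions in 4–8 weeks, stratified evenly across the two sides of a
  configurable **ground-truth rule** (half-plane, band or disk on the
  normalized indicator plane) so that cohorts satisfy the both-outcomes
  inclusion prerequisite; %PBT is 100 ± a margin drawn uniformly from
  (0.1, 6] percentage points — the spread observed in published cohort
  tables — with the sign following the rule, optionally flipped with
  probability `label_noise`.

The rule's true adaptation/maladaptation area ratio is computed exactly by
polygon clipping, giving the recovery target.

### What the validation shows — and what it does not

With 20 simulated athletes, a half-plane rule and zero label noise, every
competition week lies in its own region (mean goodness of fit 100%) and
the cohort-level GAPI — the ratio of pooled mean member areas, a
ratio-of-means estimator chosen because the mean of per-athlete ratios is
Jensen-biased upward when the truth is 1 — recovers the rule's area ratio
within 20%. On uniformly scattered weeks at n = 24 the single-fit GAPI
recovers the ratio within 15% in expectation over replicated draws,
though a single 24-point draw can deviate by a third: with samples this
small the index is a coarse summary, not a precise estimate.

Passing these tests shows the construction is internally consistent and
unbiased under its own assumptions. It does **not** show that real
seasons satisfy those assumptions: real indicator points need not scatter
across the square, competition scheduling is not stratified by outcome,
and %PBT margins are not independent of training state.

## Known limitations

* **Training-set fit is nearly insensitive to label noise.** The
  nearest-hull construction with criterion-selected cluster counts can
  isolate a contradictory point as a singleton pattern whose buffered disk
  wins its own grid cell, so goodness of fit on the *training* weeks stays
  at 100% even when labels are flipped at random (at a 30% flip rate the
  cohort mean drops only a few points, when multiple flips collide). Low
  published goodness-of-fit values for this family of models arise from
  deliberately restricting the number of separated regions; with the
  criterion-driven cluster counts used here the restriction rarely binds
  at n ≤ 8. Goodness of fit should therefore be read as a consistency
  diagnostic, not an error estimate — there is no train/validation split
  at these sample sizes.
* **Extrapolation.** Far from the data, region membership is decided by
  distance to the nearest hull; GAPI consequently depends on where the
  season's points sit in the square, not only on the separating boundary.
* **Two indicators at a time.** The construction is deliberately
  two-dimensional for readability; a higher-dimensional variant would
  need different machinery and loses the graphical interpretation.
* The original description of this family of models mentions projecting
  the three time series by their Hausdorff–Besicovitch dimensions; no
  computable recipe accompanies that remark, and the package embeds the
  raw normalized triplets directly.

## Validation study sizes

The shipped tests fit single models at grid 64–128 and cohort studies of
20 athletes with 50-replicate ensembles (collapsed analytically at zero
noise); the acceptance script runs the same cohort design at three label
noise levels. These sizes were chosen so the full validation completes in
a few minutes on a laptop while keeping Monte-Carlo error well inside the
stated tolerances.
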