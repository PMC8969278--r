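---
title: "Methods: footfall reconstruction, gait features and leakage-aware classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footfall reconstruction, gait features and leakage-aware classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gaitmat` turns raw instrumented-walkway sensor activations into
per-footfall gait features and evaluates how well those features separate
patient-like from control-like gait. This vignette documents the models,
the parameters that matter, the numerical choices, and what the bundled
simulator does and does not emulate.

## 1. The raw data model

A walkway export has one row per sensor activation sample: time (s),
integer grid coordinates, pressure (device units), plus device annotations
(foot type, foot count, footfall id, pass index). The mat is 90 × 420 cm
at a 1.27 cm pitch; indices are 0-based at cell centres, the y axis is the
long (walking) axis, and index × 1.27 converts to centimetres.

When a cell is sampled repeatedly during a stance, only the timestamp of
maximum pressure is kept (`reduce_to_peak()`). Two choices here are not
dictated by the data format:

* **Tie-break**: equal maximal pressures keep the *earliest* time —
  deterministic and consistent with first-contact semantics.
* **Activation episodes**: a cell quiet for more than 0.2 s (default
  `episode_gap`) and then re-activated starts a new episode, because one
  cell can be struck by two different footfalls in a pass. 0.2 s is well
  below any plausible same-foot re-contact interval at walking speed and
  well above the simulator's sample spacing.

The device's own footfall labels are read but never used for segmentation;
footfalls are re-derived from the point cloud so the pipeline works on
exports whose annotations are missing or untrusted.

## 2. Footfall segmentation

**Counting (k).** How many footfalls a pass contains is estimated by a gap
scan of the longitudinal projection: runs of activated rows separated by
more than two grid cells form initial segments, and fragments shorter than
0.3 × the median segment extent are merged into their nearest neighbour.
At walking speed footprints are separated by tens of centimetres along the
walking axis while cells within a footprint are contiguous, so the run
count is a reliable k. The segment centroids then *seed* Lloyd's k-means
(`stats::kmeans`), which removes initialisation randomness: the whole
segmentation is deterministic.

**Sides.** Footfalls, ordered by first contact, are given alternating
left/right labels. The labelling (out of the two possible alternations) is
the one that best agrees with the signed lateral offsets of the footfall
centroids from a total-least-squares line through them. With fewer than
three footfalls, or pathological equal offsets, the alternation is imposed
from contact order with a warning; downstream consumers treat side labels
as correct only up to a global flip.

**Footprint geometry.** The enclosing quadrilateral is the minimum-area
rotated bounding rectangle (rotating calipers over the convex hull).
A rotated rectangle — rather than an axis-aligned box — keeps the
construction meaningful for toed-in/out prints, and makes the long axis,
the three equal-length heel/mid/fore slices, and the "width across the
fore slice midpoint" all well defined. Heel vs fore orientation comes from
the pass's direction of progression, not pressure timing, so it is stable
even with degenerate timing. Sub-centroids are means of the sensor points
in each slice; the midline joins heel and fore centroids. Footprints with
fewer than three non-collinear points, or with an empty slice, are
excluded with a logged reason.

## 3. Feature definitions and conventions

Some reference points are named but not constructed in common usage; the
package fixes them as:

* **heel center** = heel-slice sub-centroid; **midline midpoint** =
  midpoint of the heel→fore centroid segment.
* **Step length** is the longitudinal (walkway-axis) component between
  consecutive opposite-foot heel centers; **stride length** is the full
  Euclidean heel-to-heel distance of same-side prints. The two quoted
  definitions differ on purpose and are implemented differently.
* **Step width** is the lateral (perpendicular-to-walkway) component
  between consecutive midline midpoints. A straight-line distance would be
  dominated by the longitudinal term and nearly collinear with step
  length; the lateral component is the field-standard meaning.
* **Toe angle** is the signed angle between the line of progression (this
  heel center to the next same-side heel center) and the footprint
  midline, positive when the toes point laterally outward. The sign
  convention (out = positive) is a package choice; flip it by negating the
  column.
* **Toe direction** encodes that sign as a binary category: 0 for
  negative, 1 for ≥ 0.
* **LOP deviation angle** is the unsigned angle in [0°, 90°] between the
  mat's long axis and the segment joining the overall centroids of two
  consecutive same-side prints. Overall centroids (not heel centers) are
  used; heel centers would be a defensible alternative.
* **Foot length** = 1.5 × heel–fore sub-centroid distance. For a uniform
  rectangular print the slice centroids sit at 1/6 and 5/6 of the length,
  so the multiplier is exact there; it is applied verbatim everywhere.
* **Hull / BOS area**: convex-hull area of one print's points, and of the
  pooled points of a print and its predecessor.
* Temporal features follow the contact-time definitions (stance = last −
  first contact; double support = current toe-off minus next heel strike,
  clipped at zero with a warning when a flight phase appears; single
  support = next same-foot heel strike minus current toe-off).

Step/stride quantities look backwards, toe angle / LOP deviation / support
times look forwards, so boundary footfalls carry missing values; rows with
any missing selected feature are dropped before modelling (counts logged).

## 4. The synthetic walkway

`generate_cohort()` draws subject-level gait parameters from
class-conditional Gaussian profiles (80 % of each stated sd between
subjects, 60 % within — the quadratures sum to 1), plans alternating
footfall poses advancing along the mat, and rasterises each pose: every
grid cell whose centre falls inside the rotated foot outline emits
rise/peak/fall pressure samples (0.03 s apart). The per-cell peak time
maps the cell's position along the foot axis linearly onto the stance
window, so heel cells peak before fore cells and the earliest/latest peak
timestamps recover the true contacts — peak-timestamp reduction is
therefore meaningful, not a no-op. A pass is truncated when the next
outline would leave the mat, as a finite walkway truncates a real pass.

Default profiles: the control-like profile walks with ~62 ± 4 cm steps,
9 ± 2 cm step width, 7 ± 2° toe-out, 0.54 ± 0.04 s step time and
0.62 ± 0.05 s stance; the patient-like profile with ~48 ± 7 cm steps,
13 ± 3 cm width, larger toe-angle variance (9 ± 4°), slower timing
(0.66 ± 0.07 s / 0.80 ± 0.07 s) and more path drift. These magnitudes are
generic adult-gait values with an impairment pattern of shorter, wider,
slower, more variable steps; they are test fixtures, not clinical claims.

Ground truth stores, per footfall, the feature values computed from the
planned *continuous* geometry (rectangle slice centroids at L/6, L/2,
5L/6) and, for the area features, from the emitted cell sets — the
features are defined on sensor points, so the discrete footprint is the
truth and discretisation convergence is checked separately (hull area
converges to the outline area as the pitch shrinks).

What the simulator does **not** emulate: realistic pressure magnitudes and
per-region loading, partial footprints at mat edges, toe-walking and other
atypical contact patterns, turning or variable-speed passes, and any
correlation structure between features beyond what the geometric
construction induces. Passing tests therefore demonstrate that the
pipeline recovers what it is designed to recover — not that the default
profiles match any clinical population.

## 5. Preprocessing and feature selection

Two feature sets are defined: the *standard* set (13 spatiotemporal
numerics + foot type) and the *augmented* set (the same minus the signed
toe angle, plus toe-angle magnitude, foot length/width/area, hull area,
BOS area, LOP deviation, with foot type and toe direction categorical).

Per training fold, in order: SMOTE balancing to equal class counts
(synthetics interpolate a minority row towards one of its k = 5 nearest
minority neighbours; categorical columns are copied from the seed row —
an SMOTE-NC-style simplification), z-scaling fitted on the balanced
training rows (population sd, i.e. divisor n; any consistent choice works
and this one is documented), ANOVA-F scoring, a greedy Pearson correlation
filter at |r| ≥ 0.8 that visits features in descending F order and drops
the lower-F member of every offending pair (deterministic and
signal-preserving; the ordering rule is a package choice), re-ranking of
survivors, and a cross-validated subset-size search: for every prefix size
of the ranked list, grouped five-fold CV with a default-configuration SVM
measures accuracy, and the best size wins with ties to the smallest.
Categorical features bypass the numeric machinery and are re-appended at
the end. Test folds are transformed with training statistics only; a
leakage test (shuffling test labels changes nothing fitted) is part of the
suite. Whether balancing should precede selection inside each fold is
genuinely ambiguous in common practice; this order is the default and the
components are exposed individually for other arrangements.

Edge cases: zero-variance columns are flagged and centred, never divided
by zero; undefined correlations count as zero with a warning; a feature
with zero within-group variance and distinct means gets an infinite F and
ranks first — a perfect separator is maximal information, not an error.

## 6. Models and evaluation

Grouped k-fold cross-validation assigns whole visits to folds (balanced
in group counts, ±1), so no subject's rows straddle train and test.
Classifiers: penalised logistic regression (`glmnet`; penalty l1/l2/
elasticnet mapped to α = 1/0/0.5, cost C mapped to λ = 1/(C·n) — solver
names from other ecosystems are plumbing, not hyperparameters, and have no
R equivalent), SVM (`e1071`, kernels poly/rbf/sigmoid), and gradient-
boosted trees (`xgboost`, depth/eta/objective, single-threaded for
determinism). Default settings are the best-performing combination per
algorithm on the standard set (LR l2 C = 1; SVM rbf C = 3; XGB depth 3,
eta 0.3, logistic); `default_grid()` holds the full published search
spaces and `grid_search()` runs an exhaustive grouped inner-CV search with
ties to the first combination in grid order.

Each footfall row is the evaluation unit. Test predictions are pooled over
outer folds (micro-averaged) rather than averaged per fold — per-fold
accuracies are also reported. Metrics are the confusion-count percentages
(accuracy, precision, recall, F1), with zero-denominator metrics reported
missing, never zero. Decision scores are class probabilities for LR/XGB
and the signed margin for SVM; ROC sweeps all distinct thresholds with
trapezoidal AUROC (equal to Mann–Whitney concordance), and AUPRC is
step-wise average precision.

## 7. Problem sizes and determinism

The test suite exercises: geometry oracles on 100 random clouds of ≤ 50
points; noise-free recovery on a 4-subject × 2-pass cohort; segmentation
fidelity on 54 noisy passes; 1000 ANOVA columns and 100 score sets against
closed-form oracles; and end-to-end experiments on 40-subject cohorts
(~6:1 class ratio, three passes each, several hundred usable rows) — sizes
at which every statistical property under test is already stable. All
randomness flows from explicit integer seeds through an RNG-state-
preserving helper; identical seeds reproduce experiments byte for byte.

## 8. Known limitations

* Whole-pass k-means assumes footprints are spatially compact and
  separated; heavily overlapping prints (shuffling gait) would need
  time-aware clustering.
* Step length/width use the mat's long axis as the walking direction;
  strongly diagonal passes bias them (stride quantities, being Euclidean
  or perpendicular distances, are unaffected).
* The double-support definition pairs a footfall only with its immediate
  successor; pathologies with double floating phases collapse to zero.
* SMOTE interpolation treats the numeric feature space as Euclidean after
  scaling; no metric learning is attempted.
* The simulator's Gaussian, per-parameter noise cannot produce the
  within-subject temporal autocorrelation of real gait; classification
  results on synthetic cohorts bound what the pipeline can do under its
  own assumptions, nothing more.
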