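---
title: "Adaptive neighborhood rough sets: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive neighborhood rough sets: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anrs)
```

## The problem

Clinical and biomedical tables are frequently *hybrid*: a record mixes
numeric measurements (spectral power of an accelerometer axis, a lab
value) with categorical descriptors (a symptom code, a device state).
Classical rough-set classification needs discretized attributes, and
numeric pipelines need categorical attributes recoded as numbers; both
conversions lose information. Neighborhood rough sets replace the
equivalence classes of classical rough sets with distance balls
(δ-neighborhoods), which handle numeric attributes natively — provided a
distance that also treats categorical attributes gradedly, and a sensible
choice of δ.

## The model

### Hybrid distance

For condition attributes split into numeric and categorical sets, the
distance between records $x$ and $y$ is

$$d(x,y) = \left[\sum_{i \in \text{num}} w_i
  \left(\frac{|x_i - y_i|}{4\sigma_i}\right)^2
  + \sum_{i \in \text{cat}} w_i\, L_i(x_i, y_i)^2\right]^{1/2}$$

* $\sigma_i$ is the **population** standard deviation (divisor $n$) of
  attribute $i$, fitted on the training partition only and never refitted
  on test data — the only fitted quantity in the model. Scaling by
  $4\sigma_i$ keeps all but extreme outliers inside a unit-scale term.
  A constant attribute has $\sigma_i = 0$ and contributes nothing (it
  cannot discriminate); the fit flags it.
* $L_i$ is the Levenshtein edit distance between the two category tokens,
  divided (by default; `normalize_lev`) by the longer token length, so
  categorical terms also live on $[0,1]$. The graded distance is the point:
  0/1 mismatch coding makes all distinct categories equidistant, which
  produces unrealistic neighborhoods.
* $w_i \ge 0$ are user-supplied attribute weights, default 1. No weight
  learning is provided — weighting is configuration, not estimation.

The pure-numeric and pure-categorical cases each have an obvious form; how
a record containing *both* kinds combines them is a genuine design choice.
We place the squared categorical terms under the same radical as the
numeric ones: the combination is symmetric in the two kinds and reduces
exactly to each pure case when the other set is empty. With every
$\sigma_i = 1/4$ and unit weights the numeric part is plain Euclidean
distance, which the tests use as a closed-form check.

### Adaptive threshold

The neighborhood of a query is every training record within

$$\delta = \min_D + r \cdot R_D,$$

where $\min_D$ is the smallest query-to-training distance (local
information), $R_D = \max_D - \min_D$ their range (global information) —
"range" in the standard statistical sense — and $r \ge 0$ a dimensionless
multiplier, default $0.002$. Ties at exactly $\delta$ are included. The
argmin records always qualify, so neighborhoods are never empty, and
membership is monotone non-decreasing in $r$. At $r = 0$ classification
degenerates to a nearest-record vote; at $r \ge 1$ every record joins.

### Approximations and classification

Granulating a labeled table (each record's neighborhood built against the
full table, self included — hence $\min_D = 0$ and $\delta = r R_D$) gives
per class $c$ the lower approximation (records whose neighborhood is
entirely class $c$), the upper approximation (neighborhood intersects
class $c$), and the boundary region (union of uppers minus union of
lowers). Self-inclusion is deliberate: granules are defined over the whole
universe, and excluding self would make lower approximations unstable.
Every training record acts as a rule whose applicability is
distance $\le \delta$; a test record is labeled by plurality vote among
the applicable rules. Vote ties are broken deterministically: smaller mean
member distance first, then the lexicographically smallest label. The
all-pairs granulation is quadratic in the record count; no pruning is
attempted.

## Evaluation harnesses

`cv_anrs()` does stratified k-fold cross-validation (default $k = 10$)
under a caller-supplied seed, refitting $\sigma_i$ on each training split
to avoid leakage. Stratification is a variance-reduction choice at small
$n$; classes smaller than $k$ are simply absent from some folds.
`holdout_anrs()` reproduces fixed train:test split shapes, and
`radius_sweep()` reruns CV over a radius grid on *identical* folds so that
differences isolate the threshold choice. All three are bit-reproducible
given their seeds.

## What the generators emulate — and what they do not

`simulate_hybrid_table()` emulates mixed-type benchmark tables: numeric
attributes are class-conditional Gaussians with unit spread and centers
`separation` apart, so `separation` is a signal-to-noise ratio; each
categorical attribute has one canonical token per class from a fixed
syllable vocabulary, emitted with probability `cat_fidelity`, otherwise a
uniformly random decoy. Decoys sit at *graded* edit distances from the
canonical tokens — chosen precisely so the Levenshtein structure of the
distance is exercised rather than a match/mismatch pattern. `label_noise`
flips labels after the features are drawn. Defaults
(`separation = 2`, `cat_fidelity = 0.9`, `label_noise = 0`) give a
moderately overlapping two-class problem typical of the UCI-style tables
this stands in for.

`simulate_tremor_signal()` emulates one tri-axial accelerometer at
62.5 Hz, the sampling rate of the wireless wearable deployment this
mirrors: each axis is a sinusoid at the tremor frequency with an
axis-specific phase plus Gaussian noise. The 4–6 Hz default band for
per-signal frequencies in `simulate_tremor_dataset()` is a physiological
convention for resting tremor, not a measured value.
`extract_fft_features()` uses a rectangular window and a one-sided reading
of the two-sided periodogram — the simplest reproducible convention — and
emits per axis the dominant (non-DC) frequency, the total power (equal to
the time-domain mean square by Parseval's identity, which the tests check
at $10^{-6}$ relative tolerance), and per-band power fractions.

Neither generator models attribute correlation, non-Gaussian numeric
noise, drifting tremor frequency, harmonics, or sensor artifacts. Passing
tests on this synthetic material therefore demonstrate correctness of the
*method's mechanics* (distances, thresholds, approximations, voting,
harness plumbing) and qualitative behavior (accuracy decays with overlap
and label noise; spectrally distinct populations separate), not clinical
performance on real recordings.

## Numerical and policy choices

* **Missing values**: numeric cells take the column mean; categorical
  cells take the literal token `"?"`, which the edit distance then treats
  as an ordinary short string. This keeps every record usable; benchmark
  usage of tables with missing values rarely states a policy, so this one
  is declared, not inherited. A numeric column that is entirely missing is
  a configuration error.
* **CSV kind inference**: a column is numeric only if *every* non-missing
  cell parses as a real number — coded categories like `"1a"` stay
  categorical. Inference is idempotent and round-trips (numerics are
  written with 17 significant digits).
* **Categorical comparison** is case-sensitive with no trimming, for
  determinism.
* **Record identity** is the 1-based row index in file order (R's native
  indexing; index sets returned by the approximation functions use it).
* **Degenerate inputs**: empty distance lists, unlabeled records in
  granulation, and empty training tables are contract violations;
  zero-range distance lists give $\delta = \min_D$ and an all-member
  neighborhood.

## Problem sizes used in validation

The shipped tests validate the edit distance against an independent
dynamic-programming oracle on 1000 random pairs (length ≤ 12), the
approximations against brute-force enumeration on 200 random tables of at
most 25 records, the $r = 0$ classifier against a nearest-neighbor oracle
on 100 random splits, and the harnesses on synthetic tables of 80–400
records; the tremor analogue uses 60 four-second signals. These sizes were
chosen so the whole suite runs comfortably on a laptop while still
exercising every code path at the scales where brute-force cross-checks
remain exact.

## Known limitations

* All-pairs distance computation: no indexing or pruning, so granulating
  very large tables is quadratic in time and memory.
* No attribute reduction or weight learning; `attributes` subsets and
  `weights` are exposed as configuration only.
* The ARFF reader supports the dense dialect with unquoted fields; sparse
  rows are rejected.
* Multi-class behavior is implemented and tested, but the radius default
  `r = 0.002` was chosen for two-class benchmark-style tables; heavily
  imbalanced or many-class problems may warrant a sweep
  (`radius_sweep()`) before trusting it.
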