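# anrs — adaptive neighborhood rough sets for hybrid data

`anrs` classifies **hybrid decision tables** — records mixing numeric and
categorical condition attributes with one categorical decision attribute —
without discretizing the numeric columns or numerically recoding the
categorical ones. It is aimed at biomedical and clinical data-mining
settings (the motivating application is accelerometer-based behavioral
monitoring of Parkinson's patients) where both kinds of attribute carry
practical meaning that conversion would destroy.

## The method

The classifier is a neighborhood rough-set (NRS) model built on three
ingredients:

**Hybrid distance.** For records *x*, *y* with numeric attributes scaled by
four population standard deviations (bounding outlier influence) and
categorical attributes compared by Levenshtein edit distance (optionally
divided by the longer string length so both kinds of term live on a
comparable scale):

    d(x, y) = [ Σ_num  w_i (|x_i − y_i| / 4σ_i)²  +  Σ_cat  w_i L_i(x_i, y_i)² ]^½

The graded edit distance matters: 0/1 mismatch coding treats `"mild"` vs
`"milder"` the same as `"mild"` vs `"severe"`, which distorts the
neighborhood space.

**Adaptive threshold.** A query's neighborhood radius blends local and
global information about its distances to the training set:

    δ = min_D + r · R_D

where `min_D` is the nearest-record distance, `R_D = max_D − min_D` is the
distance range, and `r` (default 0.002) is the only tuning knob. `r = 0`
collapses to nearest-record classification; large `r` floods the
neighborhood with the whole table.

**Rough-set approximations and voting.** Granulating a labeled table with
these neighborhoods gives, per class, a lower approximation (records whose
neighborhood is purely that class), an upper approximation (records whose
neighborhood touches it), and the boundary region between them — the zone
where classes are indiscernible at radius `r`. A test record is classified
by majority vote inside its neighborhood, with deterministic tie-breaking
(smaller mean member distance, then lexicographically smallest label).

## Worked example

```r
library(anrs)

tab <- simulate_hybrid_table(n = 120, n_numeric = 2, n_categorical = 2,
                             separation = 3, cat_fidelity = 0.9,
                             label_noise = 0.05, seed = 42)
fit <- anrs(tab, r = 0.002)
summary(fit, r = 0.2)
#> Adaptive neighborhood rough-set classifier
#>   120 training records, 4 condition attributes (2 numeric, 2 categorical)
#>   radius multiplier r = 0.002; classes: c1, c2
#> Rough-set approximations at r = 0.2 over 120 records
#>   class c1         lower   15  upper   64
#>   class c2         lower   56  upper  105
#>   boundary region: 49 record(s); quality = 0.592

cv_anrs(tab, k = 10, seed = 1)
#> 10-fold cross-validation (r = 0.002, seed = 1)
#>   fold accuracies: 0.846 1.000 0.917 1.000 1.000 0.917 0.833 1.000 0.909 1.000
#>   mean accuracy: 0.9422
```

The summary says that at radius `r = 0.2`, 71 of the 120 records live in a
pure-class neighborhood (quality 0.592) while 49 sit in the boundary
region where the two classes overlap; cross-validated accuracy at the
default adaptive radius is 94.2%. The generator plants class centers 3
within-class standard deviations apart and flips 5% of labels, so neither
number should be 1.

Real tables come in through `read_arff()` (the format produced by
FFT-featurizing accelerometer signals) or `read_hybrid_csv()`; the tremor
side of the pipeline is `simulate_tremor_signal()` →
`extract_fft_features()` → `simulate_tremor_dataset()`.

A command-line front end wrapping the same functions ships at
`system.file("cli", "anrs.R", package = "anrs")` with subcommands `cv`,
`predict`, `sweep`, `approx` and `simulate`.

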