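Package: anrs
Title: Adaptive Neighborhood Rough Sets for Hybrid Data Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Neighborhood rough-set classification for hybrid decision
    tables mixing numeric and categorical condition attributes.  Distances
    combine 4-sigma-normalized Euclidean terms for numeric attributes with
    (optionally length-normalized) Levenshtein terms for categorical
    attributes; the neighborhood radius is chosen adaptively per query from
    the minimum and the range of the query-to-training distances.  Provides
    lower/upper approximations and boundary regions of a decision, a
    majority-vote classifier with k-fold cross-validation, holdout and
    radius-sweep harnesses, ARFF and CSV input/output, a synthetic
    hybrid-table generator, and a tri-axial tremor-signal simulator with
    FFT feature extraction for desk-scale evaluation of the method on
    accelerometer-style data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    foreign,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
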