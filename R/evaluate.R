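#' Stratified k-fold cross-validation of the ANRS classifier
#'
#' Folds are stratified by class under a caller-supplied seed.  Distance
#' parameters (the per-attribute sigmas) are refitted on each training
#' split, so no test information leaks into the scaling.  The report's
#' mean accuracy is the arithmetic mean of the fold accuracies (k = 10 is
#' the conventional default).
#'
#' @param table a fully labeled `"hybrid_table"`.
#' @param k number of folds, `>= 2` and `<= n` (default 10).
#' @param r radius multiplier (default 0.002).
#' @param seed integer seed controlling the fold assignment.
#' @param stratify stratify folds by class (default `TRUE`); classes with
#'   fewer than `k` members are simply absent from some folds.
#' @param weights,normalize_lev passed to the per-fold fits.
#' @return an object of class `"anrs_cv"`: `k`, `r`, `seed`,
#'   `fold_accuracies`, `mean_accuracy`, `fold_sizes`.
#' @export
#' @examples
#' tab <- simulate_hybrid_table(n = 80, separation = 6, seed = 2)
#' cv_anrs(tab, k = 5, seed = 7)
cv_anrs <- function(table, k = 10, r = 0.002, seed = 1, stratify = TRUE,
                    weights = NULL, normalize_lev = TRUE) {
  fold <- make_folds(table, k, seed, stratify)
  acc <- cv_with_folds(table, fold, r, weights, normalize_lev)
  structure(
    list(k = as.integer(k), r = r, seed = as.integer(seed),
         fold_accuracies = acc, mean_accuracy = mean(acc),
         fold_sizes = as.integer(tabulate(fold, nbins = k))),
    class = "anrs_cv"
  )
}

#' @export
print.anrs_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (r = %g, seed = %d)\n", x$k, x$r, x$seed))
  cat("  fold accuracies:", paste(sprintf("%.3f", x$fold_accuracies), collapse = " "), "\n")
  cat(sprintf("  mean accuracy: %.4f\n", x$mean_accuracy))
  invisible(x)
}

make_folds <- function(table, k, seed, stratify = TRUE) {
  if (!inherits(table, "hybrid_table")) stop_contract("'table' must be a hybrid_table")
  lab <- table_labels(table)
  if (is.null(lab) || anyNA(lab)) stop_contract("table must be fully labeled")
  n <- n_records(table)
  if (!is_count(k) || k < 2) stop_config("'k' must be an integer >= 2")
  if (k > n) stop_config("'k' (", k, ") exceeds the record count (", n, ")")
  with_seed(seed, {
    fold <- integer(n)
    if (stratify) {
      for (cl in unique(lab)) {
        idx <- which(lab == cl)
        ids <- rep_len(seq_len(k), length(idx))
        fold[idx] <- ids[sample.int(length(ids))]
      }
    } else {
      ids <- rep_len(seq_len(k), n)
      fold <- ids[sample.int(n)]
    }
    fold
  })
}

cv_with_folds <- function(table, fold, r, weights = NULL, normalize_lev = TRUE) {
  k <- max(fold)
  lab <- table_labels(table)
  vapply(seq_len(k), function(f) {
    test_idx <- which(fold == f)
    if (!length(test_idx)) return(NA_real_)
    fit <- anrs.hybrid_table(subset_records(table, fold != f), r = r,
                             weights = weights, normalize_lev = normalize_lev)
    pred <- predict(fit, subset_records(table, test_idx)$data)
    mean(pred == lab[test_idx])
  }, numeric(1))
}

#' Holdout evaluation of the ANRS classifier
#'
#' Shuffles the table under `seed`, trains on the first `n_train` records
#' and tests on the next `n_test`, returning the fraction of correct
#' predictions.  This mirrors the fixed train:test split shapes commonly
#' reported for the UCI benchmark tables.
#'
#' @param table a fully labeled `"hybrid_table"`.
#' @param n_train,n_test split sizes; `n_train + n_test <= n`.
#' @param r radius multiplier.
#' @param seed integer shuffle seed.
#' @param weights,normalize_lev passed to the fit.
#' @return accuracy in \[0, 1\].
#' @export
holdout_anrs <- function(table, n_train, n_test, r = 0.002, seed = 1,
                         weights = NULL, normalize_lev = TRUE) {
  if (!inherits(table, "hybrid_table")) stop_contract("'table' must be a hybrid_table")
  lab <- table_labels(table)
  if (is.null(lab) || anyNA(lab)) stop_contract("table must be fully labeled")
  n <- n_records(table)
  if (!is_count(n_train) || !is_count(n_test) || n_train + n_test > n)
    stop_config("'n_train' + 'n_test' must not exceed the record count (", n, ")")
  perm <- with_seed(seed, sample.int(n))
  tr <- perm[seq_len(n_train)]
  te <- perm[n_train + seq_len(n_test)]
  fit <- anrs.hybrid_table(subset_records(table, tr), r = r, weights = weights,
                           normalize_lev = normalize_lev)
  pred <- predict(fit, subset_records(table, te)$data)
  mean(pred == lab[te])
}

#' Cross-validated accuracy across a grid of radius multipliers
#'
#' Runs [cv_anrs()] once per radius on identical folds (the same seed), so
#' differences across radii reflect the threshold choice only.  `r = 0`
#' uses purely local information (nearest-record neighborhoods); larger
#' values blend in the global distance range.
#'
#' @param table a fully labeled `"hybrid_table"`.
#' @param radii non-empty numeric vector of distinct radii `>= 0`.
#' @param k folds (default 10).
#' @param seed fold seed.
#' @param weights,normalize_lev passed to the per-fold fits.
#' @return a data frame of class `"anrs_sweep"` with columns `r` and
#'   `mean_accuracy` (one row per radius), with attributes `k` and `seed`.
#' @export
radius_sweep <- function(table, radii, k = 10, seed = 1, weights = NULL,
                         normalize_lev = TRUE) {
  if (!is.numeric(radii) || !length(radii))
    stop_config("'radii' must be a non-empty numeric vector")
  if (any(!is.finite(radii)) || any(radii < 0))
    stop_config("all radii must be finite and >= 0")
  if (anyDuplicated(radii)) stop_config("duplicate radii are not allowed")
  fold <- make_folds(table, k, seed)
  acc <- vapply(radii, function(r)
    mean(cv_with_folds(table, fold, r, weights, normalize_lev)), numeric(1))
  structure(data.frame(r = radii, mean_accuracy = acc),
            class = c("anrs_sweep", "data.frame"), k = k, seed = seed)
}

#' @export
plot.anrs_sweep <- function(x, ...) {
  graphics::plot(x$r, x$mean_accuracy, type = "b", xlab = "radius multiplier r",
                 ylab = "mean CV accuracy", ...)
  invisible(x)
}
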