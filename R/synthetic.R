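#' Generate a synthetic hybrid decision table
#'
#' Emulates the structure of mixed-type benchmark tables with controllable
#' difficulty.  Records are split (near-)evenly over `n_classes` classes.
#' Each numeric attribute is drawn from a class-conditional Gaussian with
#' unit spread and class centers `separation` apart, so `separation` is the
#' between-class distance in units of within-class spread.  Each
#' categorical attribute has one canonical token per class (drawn from a
#' fixed syllable vocabulary, so decoys sit at graded Levenshtein
#' distances): a record emits its class's canonical token with probability
#' `cat_fidelity`, else a uniformly random decoy token.  Finally each label
#' is flipped to a different class with probability `label_noise`
#' (features keep following the true class).  Fully deterministic given
#' `seed`.
#'
#' @param n record count (`>= n_classes`).
#' @param n_numeric,n_categorical attribute counts (at least one in total).
#' @param n_classes number of decision classes, `>= 2`.
#' @param separation non-negative class-center distance per numeric
#'   attribute (default 2).
#' @param cat_fidelity probability a categorical token is canonical
#'   (default 0.9).
#' @param label_noise label-flip probability (default 0).
#' @param seed integer seed.
#' @return a labeled `"hybrid_table"` with decision attribute `"class"`.
#' @export
#' @examples
#' simulate_hybrid_table(n = 20, n_numeric = 2, n_categorical = 1, seed = 1)
simulate_hybrid_table <- function(n, n_numeric = 2, n_categorical = 2,
                                  n_classes = 2, separation = 2,
                                  cat_fidelity = 0.9, label_noise = 0,
                                  seed = 1) {
  if (!is_count(n)) stop_config("'n' must be a positive integer")
  if (!is_count(n_classes) || n_classes < 2) stop_config("'n_classes' must be >= 2")
  if (n < n_classes) stop_config("'n' must be at least 'n_classes'")
  for (nm in c("n_numeric", "n_categorical")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop_config("'", nm, "' must be a non-negative integer")
  }
  if (n_numeric + n_categorical < 1)
    stop_config("need at least one condition attribute")
  if (!is_number(separation) || separation < 0)
    stop_config("'separation' must be >= 0")
  for (nm in c("cat_fidelity", "label_noise")) {
    v <- get(nm)
    if (!is_number(v) || v < 0 || v > 1)
      stop_config("'", nm, "' must be a probability in [0, 1]")
  }
  classes <- paste0("c", seq_len(n_classes))
  pool <- token_pool(n_classes + max(4L, n_classes))
  with_seed(seed, {
    true_idx <- rep_len(seq_len(n_classes), n)[sample.int(n)]
    df <- list()
    for (j in seq_len(n_numeric)) {
      df[[paste0("num", j)]] <-
        stats::rnorm(n, mean = (true_idx - 1) * separation, sd = 1)
    }
    for (j in seq_len(n_categorical)) {
      canonical <- pool[true_idx]
      decoy <- vapply(true_idx, function(ci)
        sample(pool[-ci], 1L), character(1))
      use_canon <- stats::runif(n) < cat_fidelity
      df[[paste0("cat", j)]] <- ifelse(use_canon, canonical, decoy)
    }
    lab_idx <- true_idx
    flip <- stats::runif(n) < label_noise
    if (any(flip)) {
      lab_idx[flip] <- vapply(true_idx[flip], function(ci) {
        others <- seq_len(n_classes)[-ci]
        others[sample.int(length(others), 1L)]
      }, integer(1))
    }
    df[["class"]] <- classes[lab_idx]
    as_hybrid_table(as.data.frame(df, stringsAsFactors = FALSE),
                    decision = "class")
  })
}

# Deterministic vocabulary of pronounceable tokens with graded pairwise
# edit distances (2-3 syllables from a small syllabary).
token_pool <- function(m) {
  sy <- c("ka", "ro", "mi", "ta", "lu", "ne", "si", "do", "va", "pe")
  two <- as.vector(outer(sy, sy, paste0))
  pool <- unique(c(two, as.vector(outer(two, sy, paste0))))
  if (m > length(pool)) stop_config("token pool exhausted (", m, " requested)")
  pool[seq_len(m)]
}
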