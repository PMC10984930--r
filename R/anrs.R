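#' Fit an adaptive neighborhood rough-set classifier
#'
#' `anrs()` stores the labeled training table together with the fitted
#' hybrid-distance parameters and the radius multiplier `r`.  The model is
#' instance-based: a query's class is the majority vote inside its adaptive
#' neighborhood, the set of training records whose hybrid distance to the
#' query is at most \eqn{\delta = \min_D + r R_D} (see
#' [adaptive_threshold()]).  Numeric attributes enter the distance through
#' 4-sigma-normalized Euclidean terms, categorical attributes through
#' (optionally length-normalized) Levenshtein terms.
#'
#' @param x a formula (`class ~ .` or `class ~ a + b`) or a
#'   `"hybrid_table"`.
#' @param ... further arguments passed to methods.
#' @return an object of class `"anrs"` with components `table`, `params`,
#'   `r`, `classes` and `call`.
#' @seealso [predict.anrs()], [cv_anrs()], [class_approximations()]
#' @export
#' @examples
#' tab <- simulate_hybrid_table(n = 60, separation = 4, seed = 1)
#' fit <- anrs(tab)
#' fit
#' predict(fit, tab$data[1:3, ])
anrs <- function(x, ...) UseMethod("anrs")

#' @rdname anrs
#' @param data a data frame (formula method); numeric columns become
#'   numeric attributes, all others categorical.
#' @param r non-negative radius multiplier; default 0.002.
#' @param weights optional named non-negative attribute weights.
#' @param normalize_lev logical, length-normalize Levenshtein terms
#'   (default `TRUE`).
#' @export
anrs.formula <- function(x, data, r = 0.002, weights = NULL,
                         normalize_lev = TRUE, ...) {
  if (!is.data.frame(data)) stop_contract("'data' must be a data frame")
  decision <- as.character(x[[2L]])
  rhs <- attr(stats::terms(x, data = data), "term.labels")
  cols <- unique(c(rhs, decision))
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop_config("formula names column(s) absent from data: ",
                paste(miss, collapse = ", "))
  tab <- as_hybrid_table(data[, cols, drop = FALSE], decision = decision)
  out <- anrs.hybrid_table(tab, r = r, weights = weights,
                           normalize_lev = normalize_lev)
  out$call <- match.call()
  out
}

#' @rdname anrs
#' @export
anrs.hybrid_table <- function(x, r = 0.002, weights = NULL,
                              normalize_lev = TRUE, ...) {
  lab <- table_labels(x)
  if (is.null(lab) || anyNA(lab))
    stop_contract("training table must be fully labeled")
  if (!is_number(r) || r < 0) stop_config("'r' must be a single number >= 0")
  params <- fit_distance_params(x, weights, normalize_lev)
  structure(
    list(table = x, params = params, r = r,
         classes = sort(unique(lab)), call = match.call()),
    class = "anrs"
  )
}

#' @rdname anrs
#' @param decision decision column name (data-frame method).
#' @export
anrs.data.frame <- function(x, decision, r = 0.002, weights = NULL,
                            normalize_lev = TRUE, ...) {
  out <- anrs.hybrid_table(as_hybrid_table(x, decision), r = r,
                           weights = weights, normalize_lev = normalize_lev)
  out$call <- match.call()
  out
}

#' @export
print.anrs <- function(x, ...) {
  sch <- x$table$schema
  cat("Adaptive neighborhood rough-set classifier\n")
  cat(sprintf("  %d training records, %d condition attributes (%d numeric, %d categorical)\n",
              n_records(x$table), length(sch$kinds),
              sum(sch$kinds == "numeric"), sum(sch$kinds == "categorical")))
  cat(sprintf("  radius multiplier r = %g; classes: %s\n",
              x$r, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Summarize an ANRS fit by its approximation structure
#'
#' Granulates the training table at the fit's radius and reports, per
#' class, the sizes of the lower and upper approximations, plus the
#' boundary region and the classification quality (the fraction of records
#' whose neighborhood is pure).
#'
#' @param object an `"anrs"` fit.
#' @param r radius multiplier; defaults to the fit's.
#' @param ... ignored.
#' @return a `"summary.anrs"` object.
#' @export
summary.anrs <- function(object, r = object$r, ...) {
  ap <- class_approximations(object$table, r = r, params = object$params)
  structure(list(fit = object, approx = ap), class = "summary.anrs")
}

#' @export
print.summary.anrs <- function(x, ...) {
  print(x$fit)
  print(x$approx)
  invisible(x)
}

#' Classify query records with an ANRS fit
#'
#' Each query's neighborhood is formed over the training table (the query
#' itself is not a member) and its class is the plurality label among the
#' members.  Vote ties are broken deterministically: first by the smaller
#' mean member distance, then by the lexicographically smallest class
#' label.  Predictions never inspect a query's own label.
#'
#' @param object an `"anrs"` fit.
#' @param newdata a data frame or `"hybrid_table"` holding every condition
#'   attribute of the training schema (a decision column, if present, is
#'   ignored).
#' @param type `"class"` for a character vector of labels, `"votes"` for a
#'   query-by-class count matrix, `"full"` for a list of per-query
#'   predictions (label, votes, members, distances, delta, tie_broken).
#' @param r radius multiplier; defaults to the fit's.
#' @param ... ignored.
#' @return see `type`.
#' @export
predict.anrs <- function(object, newdata, type = c("class", "votes", "full"),
                         r = object$r, ...) {
  type <- match.arg(type)
  if (!is_number(r) || r < 0) stop_config("'r' must be a single number >= 0")
  qdf <- if (inherits(newdata, "hybrid_table")) newdata$data else newdata
  if (!is.data.frame(qdf)) stop_contract("'newdata' must be a data frame or hybrid_table")
  qdf <- conform_queries(qdf, object$table$schema)
  if (!nrow(qdf)) {
    return(switch(type,
                  class = character(0),
                  votes = matrix(0L, 0L, length(object$classes),
                                 dimnames = list(NULL, object$classes)),
                  full = list()))
  }
  D <- cross_distances(qdf, object$table$data, object$params)
  lab <- table_labels(object$table)
  preds <- lapply(seq_len(nrow(qdf)), function(i) {
    d <- D[i, ]
    th <- adaptive_threshold(d, r)
    members <- which(d <= th$delta)
    v <- majority_vote(lab[members], d[members], object$classes)
    list(label = v$label, votes = v$votes, tie_broken = v$tie_broken,
         members = members, distances = d[members], delta = th$delta)
  })
  switch(type,
         class = vapply(preds, `[[`, character(1), "label"),
         votes = t(vapply(preds, `[[`, stats::setNames(integer(length(object$classes)),
                                                       object$classes), "votes")),
         full = preds)
}

# Plurality vote with the deterministic tie-break cascade.
majority_vote <- function(member_labels, member_dists, classes) {
  counts <- stats::setNames(integer(length(classes)), classes)
  tab <- table(member_labels)
  counts[names(tab)] <- as.integer(tab)
  top <- names(counts)[counts == max(counts)]
  tie_broken <- length(top) > 1L
  if (tie_broken) {
    md <- vapply(top, function(cl) mean(member_dists[member_labels == cl]),
                 numeric(1))
    top <- top[md == min(md)]
    top <- sort(top)[1L]
  }
  list(label = top[1L], votes = counts, tie_broken = tie_broken)
}

# Check a query frame against the training schema: every condition
# attribute present with a coercible type; extra columns dropped.
conform_queries <- function(qdf, schema) {
  miss <- setdiff(names(schema$kinds), names(qdf))
  if (length(miss))
    stop_config("query data is missing condition attribute(s): ",
                paste(miss, collapse = ", "))
  out <- qdf[, names(schema$kinds), drop = FALSE]
  for (a in names(schema$kinds)) {
    if (schema$kinds[[a]] == "numeric") {
      v <- out[[a]]
      if (!is.numeric(v)) {
        v <- suppressWarnings(as.numeric(as.character(v)))
        if (anyNA(v) && !anyNA(out[[a]]))
          stop_config("query attribute '", a, "' is not numeric")
      }
      if (anyNA(v))
        stop_contract("query attribute '", a, "' contains missing values; ",
                      "apply the missing-value policy first")
      out[[a]] <- as.double(v)
    } else {
      out[[a]] <- as.character(out[[a]])
    }
  }
  rownames(out) <- NULL
  out
}
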