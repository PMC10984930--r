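#' Fit the parameters of the hybrid distance
#'
#' The only fitted quantities are the per-attribute dispersions
#' \eqn{\sigma_i} of the numeric attributes, taken as the population
#' standard deviation (divisor \eqn{n}) over the training records.  Numeric
#' differences are later scaled by \eqn{4\sigma_i}, which bounds the
#' influence of outliers; a constant attribute gets \eqn{\sigma_i = 0} and
#' contributes nothing to distances (it carries no discriminating
#' information), which is flagged with a message.
#'
#' @param train a non-empty `"hybrid_table"` of training records.
#' @param weights optional named non-negative weights per condition
#'   attribute; defaults to the schema weights (1 each).  A weight for an
#'   unknown attribute is a configuration error.
#' @param normalize_lev logical; divide each Levenshtein term by the longer
#'   string length of the pair so categorical terms live on \[0, 1\] like
#'   the 4-sigma-scaled numeric terms.  Default `TRUE`.
#' @return an object of class `"distance_params"` with fields `sigmas`,
#'   `weights`, `normalize_lev` and `kinds`.
#' @seealso [hybrid_distance()], [anrs()]
#' @export
fit_distance_params <- function(train, weights = NULL, normalize_lev = TRUE) {
  if (!inherits(train, "hybrid_table")) stop_contract("'train' must be a hybrid_table")
  if (!n_records(train)) stop_contract("'train' must be non-empty")
  sch <- train$schema
  w <- sch$weights
  if (!is.null(weights)) {
    if (is.null(names(weights)))
      stop_config("'weights' must be a named numeric vector")
    unknown <- setdiff(names(weights), names(sch$kinds))
    if (length(unknown))
      stop_config("weight given for unknown attribute: ",
                  paste(unknown, collapse = ", "))
    if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights < 0))
      stop_config("weights must be finite and >= 0")
    w[names(weights)] <- weights
  }
  num <- schema_attrs(sch, "numeric")
  sig <- vapply(num, function(a) {
    v <- train$data[[a]]
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  const <- num[sig == 0]
  if (length(const))
    message("constant numeric attribute(s) with sigma = 0: ",
            paste(const, collapse = ", "))
  structure(
    list(sigmas = sig, weights = w, normalize_lev = isTRUE(normalize_lev),
         kinds = sch$kinds),
    class = "distance_params"
  )
}

#' @export
print.distance_params <- function(x, ...) {
  cat("Hybrid distance parameters:", sum(x$kinds == "numeric"),
      "numeric sigma(s),", sum(x$kinds == "categorical"),
      "categorical attribute(s);",
      if (x$normalize_lev) "length-normalized" else "raw",
      "Levenshtein terms\n")
  invisible(x)
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming `a` into `b`; when either string is empty the
#' distance is the length of the other.  Vectorized elementwise over pairs.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of edit distances.
#' @export
#' @examples
#' levenshtein("flaw", "lawn")   # 2
#' levenshtein("", "abc")        # 3
levenshtein <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(utils::adist(a[i], b[i])[1L, 1L])
  out
}

# Levenshtein term as used inside the hybrid distance: optionally divided
# by the longer string length; two empty strings give 0 either way.
lev_term <- function(a, b, normalize) {
  d <- as.numeric(utils::adist(a, b))
  if (normalize) {
    m <- pmax(nchar(a), nchar(b))
    d <- ifelse(m > 0, d / m, 0)
  }
  d
}

record_values <- function(x) {
  if (inherits(x, "hybrid_table")) {
    if (n_records(x) != 1L) stop_contract("expected a single record")
    return(x$data)
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop_contract("expected a single record (one row)")
    return(x)
  }
  if (is.list(x)) return(as.data.frame(x, stringsAsFactors = FALSE))
  stop_contract("a record must be a named list, one-row data frame or one-record table")
}

check_record_attrs <- function(df, params, attrs) {
  miss <- setdiff(attrs, names(df))
  if (length(miss))
    stop_contract("record is missing attribute(s): ", paste(miss, collapse = ", "))
}

#' Numeric part of the hybrid distance
#'
#' \eqn{\sqrt{\sum_i w_i \,(|x_i - y_i| / 4\sigma_i)^2}} over the numeric
#' condition attributes; attributes with \eqn{\sigma_i = 0} contribute 0.
#'
#' @param x,y records: named lists or one-row data frames holding the
#'   numeric attributes.
#' @param params a [fit_distance_params()] object.
#' @return non-negative scalar.
#' @export
numeric_part <- function(x, y, params) {
  if (!inherits(params, "distance_params")) stop_contract("'params' must be distance_params")
  xv <- record_values(x); yv <- record_values(y)
  num <- names(params$kinds)[params$kinds == "numeric"]
  check_record_attrs(xv, params, num)
  check_record_attrs(yv, params, num)
  acc <- 0
  for (a in num) {
    s <- params$sigmas[[a]]
    if (s > 0) {
      acc <- acc + params$weights[[a]] *
        (abs(as.numeric(xv[[a]]) - as.numeric(yv[[a]])) / (4 * s))^2
    }
  }
  sqrt(acc)
}

#' Hybrid distance between two records
#'
#' Combines the numeric and categorical attributes under one radical,
#' \deqn{d(x,y) = \Big[\sum_{i \in num} w_i (|x_i - y_i| / 4\sigma_i)^2 +
#'   \sum_{i \in cat} w_i\, L_i(x_i, y_i)^2\Big]^{1/2},}
#' where \eqn{L_i} is the Levenshtein distance on attribute \eqn{i},
#' divided by the longer string length when `params$normalize_lev` is on.
#' The form reduces exactly to [numeric_part()] when no categorical
#' attributes exist and to the pure Levenshtein aggregation when no numeric
#' attributes exist.
#'
#' @inheritParams numeric_part
#' @return non-negative scalar.
#' @export
#' @examples
#' tab <- as_hybrid_table(
#'   data.frame(v = c(1, 3), s = c("on", "off"), y = c("a", "b")),
#'   decision = "y")
#' p <- fit_distance_params(tab)
#' hybrid_distance(tab$data[1, ], tab$data[2, ], p)
hybrid_distance <- function(x, y, params) {
  if (!inherits(params, "distance_params")) stop_contract("'params' must be distance_params")
  xv <- record_values(x); yv <- record_values(y)
  attrs <- names(params$kinds)
  check_record_attrs(xv, params, attrs)
  check_record_attrs(yv, params, attrs)
  as.numeric(cross_distances(xv, yv, params))
}

# Workhorse: matrix of hybrid distances between the rows of two data
# frames, vectorized per attribute.  Categorical terms go through adist on
# the unique tokens of each side only.
cross_distances <- function(query_df, ref_df, params, attributes = NULL) {
  attrs <- attributes %||% names(params$kinds)
  nq <- nrow(query_df)
  nt <- nrow(ref_df)
  acc <- matrix(0, nq, nt)
  for (a in attrs) {
    w <- params$weights[[a]]
    if (w == 0) next
    if (params$kinds[[a]] == "numeric") {
      s <- params$sigmas[[a]]
      if (s > 0) {
        d <- abs(outer(as.numeric(query_df[[a]]), as.numeric(ref_df[[a]]), "-")) / (4 * s)
        acc <- acc + w * d^2
      }
    } else {
      qa <- as.character(query_df[[a]])
      ta <- as.character(ref_df[[a]])
      uq <- unique(qa)
      ut <- unique(ta)
      L <- utils::adist(uq, ut)
      if (params$normalize_lev) {
        m <- outer(nchar(uq), nchar(ut), pmax)
        L <- ifelse(m > 0, L / m, 0)
      }
      acc <- acc + w * (L[cbind(rep(match(qa, uq), times = nt),
                                rep(match(ta, ut), each = nq))])^2
    }
  }
  sqrt(acc)
}

pairwise_distances <- function(table, params, attributes = NULL) {
  cross_distances(table$data, table$data, params, attributes)
}
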