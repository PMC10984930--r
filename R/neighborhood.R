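#' Adaptive neighborhood threshold
#'
#' The neighborhood radius for a query blends local and global information
#' about its distances to the training records:
#' \deqn{\delta = \min_D + r \cdot R_D,}
#' where \eqn{\min_D} is the smallest query-to-training distance (local)
#' and \eqn{R_D = \max_D - \min_D} is the range of those distances
#' (global).  At `r = 0` the neighborhood degenerates to the nearest
#' records; large `r` sweeps in the whole table.
#'
#' @param distances non-empty numeric vector of non-negative distances.
#' @param r non-negative radius multiplier (default 0.002).
#' @return a list with components `delta`, `min_d`, `range_d`.
#' @export
#' @examples
#' adaptive_threshold(c(0.2, 0.7, 1.2), r = 0.002)  # delta = 0.202
adaptive_threshold <- function(distances, r = 0.002) {
  if (!is.numeric(distances) || !length(distances))
    stop_contract("'distances' must be a non-empty numeric vector")
  if (any(!is.finite(distances)) || any(distances < 0))
    stop_contract("'distances' must be finite and non-negative")
  if (!is_number(r) || r < 0) stop_config("'r' must be a single number >= 0")
  mn <- min(distances)
  rg <- max(distances) - mn
  list(delta = mn + r * rg, min_d = mn, range_d = rg)
}

#' Build the adaptive neighborhood of a query record
#'
#' Computes the hybrid distance from `query` to every record of `table`
#' (optionally restricted to an attribute subset B), derives the adaptive
#' threshold via [adaptive_threshold()], and returns the information
#' granule: all records at distance `<= delta` (ties at the threshold are
#' included).  The argmin records always qualify, so the neighborhood is
#' never empty.
#'
#' @param query a record (named list or one-row data frame).
#' @param table a non-empty `"hybrid_table"`.
#' @param params a [fit_distance_params()] object fitted on `table`'s
#'   schema.
#' @param r non-negative radius multiplier.
#' @param attributes optional character vector of condition attributes
#'   (the subset B); default all.  Including the decision attribute is a
#'   configuration error.
#' @return an object of class `"anrs_neighborhood"`: `delta`, `min_d`,
#'   `range_d`, `members` (1-based record indices), `distances`, `r`,
#'   `attributes`.
#' @export
build_neighborhood <- function(query, table, params, r = 0.002, attributes = NULL) {
  if (!inherits(table, "hybrid_table")) stop_contract("'table' must be a hybrid_table")
  if (!n_records(table)) stop_contract("'table' must be non-empty")
  if (!inherits(params, "distance_params")) stop_contract("'params' must be distance_params")
  attributes <- check_attribute_subset(attributes, table$schema)
  qv <- record_values(query)
  check_record_attrs(qv, params, attributes %||% names(params$kinds))
  d <- as.numeric(cross_distances(qv, table$data, params, attributes))
  th <- adaptive_threshold(d, r)
  structure(
    list(delta = th$delta, min_d = th$min_d, range_d = th$range_d,
         members = which(d <= th$delta), distances = d, r = r,
         attributes = attributes),
    class = "anrs_neighborhood"
  )
}

#' @export
print.anrs_neighborhood <- function(x, ...) {
  cat(sprintf("Adaptive neighborhood: %d member(s), delta = %.6g (min %.6g + r %.4g * range %.6g)\n",
              length(x$members), x$delta, x$min_d, x$r, x$range_d))
  invisible(x)
}

check_attribute_subset <- function(attributes, schema) {
  if (is.null(attributes)) return(NULL)
  if (schema$decision %in% attributes)
    stop_config("the attribute subset must not contain the decision attribute '",
                schema$decision, "'")
  unknown <- setdiff(attributes, names(schema$kinds))
  if (length(unknown))
    stop_config("unknown attribute(s) in subset: ", paste(unknown, collapse = ", "))
  attributes
}

#' Rough-set approximations of the decision classes
#'
#' Granulates the labeled table: every record's neighborhood is built
#' against the full table (self included, so `min_d = 0` and
#' `delta = r * range_d`).  A record enters the lower approximation of
#' class c iff its neighborhood lies entirely inside class c, and the upper
#' approximation iff its neighborhood intersects class c.  The boundary
#' region of the decision is the union of uppers minus the union of lowers
#' — the zone where classes are indiscernible at radius `r`.
#'
#' @param table a fully labeled `"hybrid_table"`.
#' @param r non-negative radius multiplier (default 0.002).
#' @param attributes optional condition-attribute subset B.
#' @param params optional [fit_distance_params()]; fitted on `table` when
#'   omitted.
#' @param weights,normalize_lev passed to [fit_distance_params()] when
#'   `params` is omitted.
#' @return an object of class `"anrs_approximations"` with named lists
#'   `lower` and `upper` of sorted record-index vectors per class,
#'   `boundary`, `classes`, `r`, `n` and the classification `quality`
#'   (fraction of records in some lower approximation).
#' @seealso [boundary_region()]
#' @export
class_approximations <- function(table, r = 0.002, attributes = NULL,
                                 params = NULL, weights = NULL,
                                 normalize_lev = TRUE) {
  if (!inherits(table, "hybrid_table")) stop_contract("'table' must be a hybrid_table")
  lab <- table_labels(table)
  if (is.null(lab) || anyNA(lab))
    stop_contract("every record must carry a decision label")
  attributes <- check_attribute_subset(attributes, table$schema)
  params <- params %||% fit_distance_params(table, weights, normalize_lev)
  D <- pairwise_distances(table, params, attributes)
  n <- n_records(table)
  classes <- sort(unique(lab))
  # delta_i = min + r*range; the self distance 0 makes min = 0.
  delta <- apply(D, 1L, min) + r * (apply(D, 1L, max) - apply(D, 1L, min))
  lower <- stats::setNames(vector("list", length(classes)), classes)
  upper <- stats::setNames(vector("list", length(classes)), classes)
  member_classes <- lapply(seq_len(n), function(i) unique(lab[D[i, ] <= delta[i]]))
  for (cl in classes) {
    lower[[cl]] <- which(vapply(member_classes, function(s) identical(s, cl), logical(1)))
    upper[[cl]] <- which(vapply(member_classes, function(s) cl %in% s, logical(1)))
  }
  all_lower <- sort(unique(unlist(lower)))
  all_upper <- sort(unique(unlist(upper)))
  structure(
    list(classes = classes, lower = lower, upper = upper,
         boundary = setdiff(all_upper, all_lower),
         r = r, n = n, attributes = attributes,
         quality = length(all_lower) / n),
    class = "anrs_approximations"
  )
}

#' Boundary region of the decision
#'
#' `(union of upper approximations) minus (union of lower approximations)`.
#'
#' @param approx an `"anrs_approximations"` object.
#' @return sorted integer vector of record indices.
#' @export
boundary_region <- function(approx) {
  if (!inherits(approx, "anrs_approximations"))
    stop_contract("'approx' must be an anrs_approximations object")
  sort(setdiff(unique(unlist(approx$upper)), unique(unlist(approx$lower))))
}

#' @export
print.anrs_approximations <- function(x, ...) {
  cat(sprintf("Rough-set approximations at r = %g over %d records\n", x$r, x$n))
  for (cl in x$classes)
    cat(sprintf("  class %-10s lower %4d  upper %4d\n",
                cl, length(x$lower[[cl]]), length(x$upper[[cl]])))
  cat(sprintf("  boundary region: %d record(s); quality = %.3f\n",
              length(x$boundary), x$quality))
  invisible(x)
}
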