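#' Schema of a hybrid decision table
#'
#' A hybrid decision table mixes numeric and categorical condition
#' attributes with one categorical decision attribute.  The schema records,
#' in column order, the name and kind of every condition attribute, the name
#' of the decision attribute, and an optional non-negative weight per
#' condition attribute (all 1 by default) used by the hybrid distance.
#'
#' @param attributes character vector of condition-attribute names.
#' @param kinds character vector, same length, each `"numeric"` or
#'   `"categorical"`.
#' @param decision name of the decision attribute (must not be a condition
#'   attribute).
#' @param weights optional named numeric vector of non-negative attribute
#'   weights; names must be condition attributes.  Unnamed attributes get
#'   weight 1.
#' @return an object of class `"hybrid_schema"`.
#' @seealso [hybrid_table()], [as_hybrid_table()]
#' @export
#' @examples
#' hybrid_schema(c("age", "stage"), c("numeric", "categorical"), "outcome")
hybrid_schema <- function(attributes, kinds, decision, weights = NULL) {
  if (!is.character(attributes) || length(attributes) < 1L)
    stop_config("a schema needs at least one condition attribute")
  if (length(kinds) != length(attributes) ||
      !all(kinds %in% c("numeric", "categorical")))
    stop_config("'kinds' must match 'attributes' and be 'numeric' or 'categorical'")
  if (!is.character(decision) || length(decision) != 1L || !nzchar(decision))
    stop_config("'decision' must be a single attribute name")
  if (anyDuplicated(c(attributes, decision)))
    stop_config("attribute names (including the decision) must be unique")
  w <- stats::setNames(rep(1, length(attributes)), attributes)
  if (!is.null(weights)) {
    if (is.null(names(weights)) || !all(nzchar(names(weights))))
      stop_config("'weights' must be a named numeric vector")
    unknown <- setdiff(names(weights), attributes)
    if (length(unknown))
      stop_config("weight given for unknown attribute: ",
                  paste(unknown, collapse = ", "))
    if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights < 0))
      stop_config("weights must be finite and >= 0")
    w[names(weights)] <- weights
  }
  structure(
    list(kinds = stats::setNames(kinds, attributes),
         decision = decision,
         weights = w),
    class = "hybrid_schema"
  )
}

#' @export
print.hybrid_schema <- function(x, ...) {
  cat("Hybrid schema:", length(x$kinds), "condition attributes",
      sprintf("(%d numeric, %d categorical)",
              sum(x$kinds == "numeric"), sum(x$kinds == "categorical")),
      "\n  decision:", x$decision, "\n")
  invisible(x)
}

schema_attrs <- function(schema, kind = NULL) {
  nm <- names(schema$kinds)
  if (is.null(kind)) nm else nm[schema$kinds == kind]
}

#' Construct a hybrid decision table
#'
#' Binds a data frame of records to a [hybrid_schema()].  Numeric columns
#' must be finite doubles; categorical columns are stored as character.
#' Record order is preserved and the (1-based) row index is the record
#' identity used by every index set downstream.
#'
#' @param data a data frame holding every condition attribute and,
#'   optionally, the decision attribute.
#' @param schema a [hybrid_schema()].
#' @return an object of class `"hybrid_table"` with fields `data` and
#'   `schema`.
#' @export
hybrid_table <- function(data, schema) {
  if (!inherits(schema, "hybrid_schema")) stop_contract("'schema' must be a hybrid_schema")
  if (!is.data.frame(data)) stop_contract("'data' must be a data frame")
  miss <- setdiff(names(schema$kinds), names(data))
  if (length(miss))
    stop_contract("data is missing condition attribute(s): ",
                  paste(miss, collapse = ", "))
  keep <- c(names(schema$kinds), intersect(schema$decision, names(data)))
  data <- data[, keep, drop = FALSE]
  for (a in names(schema$kinds)) {
    if (schema$kinds[[a]] == "numeric") {
      v <- data[[a]]
      if (!is.numeric(v))
        stop_contract("attribute '", a, "' is declared numeric but is not")
      data[[a]] <- as.double(v)
    } else {
      data[[a]] <- as.character(data[[a]])
    }
  }
  if (schema$decision %in% names(data))
    data[[schema$decision]] <- as.character(data[[schema$decision]])
  rownames(data) <- NULL
  structure(list(data = data, schema = schema), class = "hybrid_table")
}

#' Coerce a data frame to a hybrid decision table
#'
#' Kinds are taken from the column types: numeric/integer columns become
#' numeric attributes, everything else (character, factor, logical) becomes
#' categorical.
#'
#' @param data a data frame.
#' @param decision name of the decision column (must be present).
#' @param weights optional named attribute weights, see [hybrid_schema()].
#' @return a `"hybrid_table"`.
#' @export
#' @examples
#' df <- data.frame(x = c(1, 2), tok = c("on", "off"), y = c("a", "b"))
#' as_hybrid_table(df, decision = "y")
as_hybrid_table <- function(data, decision, weights = NULL) {
  if (!is.data.frame(data)) stop_contract("'data' must be a data frame")
  if (!decision %in% names(data))
    stop_config("decision attribute '", decision, "' not found in data")
  cond <- setdiff(names(data), decision)
  if (!length(cond)) stop_config("no condition attributes besides the decision")
  kinds <- vapply(data[cond], function(v)
    if (is.numeric(v)) "numeric" else "categorical", character(1))
  hybrid_table(data, hybrid_schema(cond, kinds, decision, weights))
}

n_records <- function(table) nrow(table$data)

has_labels <- function(table) table$schema$decision %in% names(table$data)

table_labels <- function(table) {
  if (!has_labels(table)) return(NULL)
  table$data[[table$schema$decision]]
}

subset_records <- function(table, idx) {
  out <- table
  out$data <- table$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' @export
print.hybrid_table <- function(x, ...) {
  cat("Hybrid decision table:", n_records(x), "records,",
      length(x$schema$kinds), "condition attributes",
      sprintf("(%d numeric, %d categorical)\n",
              sum(x$schema$kinds == "numeric"),
              sum(x$schema$kinds == "categorical")))
  if (has_labels(x)) {
    tab <- table(table_labels(x))
    cat("  decision '", x$schema$decision, "': ",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  decision '", x$schema$decision, "': unlabeled\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.hybrid_table <- function(x, ...) x$data

#' Impute missing values in a hybrid table
#'
#' Missing numeric cells are replaced by the column mean over non-missing
#' entries; missing categorical cells by the reserved token `"?"`, treated
#' as an ordinary string by the Levenshtein distance thereafter.  A table
#' without missing cells is returned unchanged.  The number of records and
#' attributes never changes.
#'
#' @param table a `"hybrid_table"`.
#' @return the imputed `"hybrid_table"`.
#' @export
apply_missing_policy <- function(table) {
  if (!inherits(table, "hybrid_table")) stop_contract("'table' must be a hybrid_table")
  sch <- table$schema
  for (a in names(sch$kinds)) {
    v <- table$data[[a]]
    if (sch$kinds[[a]] == "numeric") {
      if (anyNA(v)) {
        if (all(is.na(v)))
          stop_config("numeric attribute '", a,
                      "' is entirely missing; no mean is defined")
        v[is.na(v)] <- mean(v, na.rm = TRUE)
        table$data[[a]] <- v
      }
    } else {
      if (anyNA(v)) {
        v[is.na(v)] <- "?"
        table$data[[a]] <- v
      }
    }
  }
  if (has_labels(table)) {
    lab <- table$data[[sch$decision]]
    if (anyNA(lab)) {
      lab[is.na(lab)] <- "?"
      table$data[[sch$decision]] <- lab
    }
  }
  table
}
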