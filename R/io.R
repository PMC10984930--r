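# Tokens treated as missing when reading CSV text.
CSV_NA_STRINGS <- c("", "?", "NA")

#' Read a hybrid decision table from an ARFF file
#'
#' Standard (dense) ARFF: `@relation`, `@attribute name numeric|{v1,...}`,
#' `@data`, with `?` as the missing marker.  Nominal and string attributes
#' map to categorical kind, numeric/real/integer to numeric kind.  Missing
#' values are imputed on read per [apply_missing_policy()].
#'
#' @param path path to an ARFF file.
#' @param decision name of the decision attribute; defaults to the last
#'   declared attribute.
#' @return a `"hybrid_table"`.
#' @export
read_arff <- function(path, decision = NULL) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  check_arff_rows(path)
  df <- tryCatch(
    foreign::read.arff(path),
    error = function(e) stop_parse("malformed ARFF file '", path, "': ",
                                   conditionMessage(e))
  )
  if (!nrow(df)) stop_parse("empty table: '", path, "' has no data rows")
  for (j in seq_along(df)) {
    if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  }
  decision <- decision %||% names(df)[length(df)]
  if (!decision %in% names(df))
    stop_config("decision attribute '", decision, "' not declared in ", path)
  tab <- as_hybrid_table(df, decision = decision)
  apply_missing_policy(tab)
}

# Pre-scan the @data section so arity errors name the offending line;
# foreign::read.arff reports these opaquely.  Quoted fields containing
# commas are not handled (none of the supported dialect needs them).
check_arff_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  low <- tolower(trimws(lines))
  n_attr <- sum(startsWith(low, "@attribute"))
  data_at <- which(low == "@data")
  if (!n_attr || !length(data_at))
    stop_parse("malformed ARFF header in '", path,
               "': need @attribute declarations and a @data marker")
  for (i in seq(from = data_at[1] + 1L, length.out = length(lines) - data_at[1])) {
    row <- trimws(lines[i])
    if (!nzchar(row) || startsWith(row, "%")) next
    if (startsWith(row, "{"))
      stop_parse("sparse ARFF rows are not supported (line ", i, ")")
    nf <- length(strsplit(row, ",", fixed = TRUE)[[1]])
    if (nf != n_attr)
      stop_parse("ARFF data row at line ", i, ": expected ", n_attr,
                 " fields, found ", nf)
  }
  invisible(TRUE)
}

#' Write a hybrid decision table to an ARFF file
#'
#' Categorical attributes (and the decision) are written as nominal
#' attributes with their observed value sets.
#'
#' @param table a `"hybrid_table"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_arff <- function(table, path) {
  if (!inherits(table, "hybrid_table")) stop_contract("'table' must be a hybrid_table")
  df <- table$data
  for (a in names(df)) {
    if (is.character(df[[a]])) df[[a]] <- factor(df[[a]])
  }
  foreign::write.arff(df, path)
  invisible(path)
}

#' Read a hybrid decision table from CSV
#'
#' A header row is mandatory.  When `schema` is omitted, column kinds are
#' inferred: a column is numeric only if every non-missing cell parses as a
#' real number, otherwise categorical (so coded categories like `"1a"` are
#' never coerced).  Missing markers are the empty string, `"?"` and `"NA"`;
#' they are imputed on read per [apply_missing_policy()].  Comparison of
#' categorical values is case-sensitive and untrimmed.
#'
#' @param path path to a CSV file (RFC-4180 style, UTF-8).
#' @param decision name of the decision column.
#' @param schema optional [hybrid_schema()] overriding kind inference.
#' @return a `"hybrid_table"` whose schema records the inferred kinds.
#' @export
read_hybrid_csv <- function(path, decision, schema = NULL) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    na.strings = CSV_NA_STRINGS, stringsAsFactors = FALSE),
    error = function(e) stop_parse("malformed CSV '", path, "': ",
                                   conditionMessage(e))
  )
  if (!ncol(df)) stop_parse("empty table: '", path, "' has no columns")
  if (!nrow(df)) stop_parse("empty table: '", path, "' has no data rows")
  if (!decision %in% names(df))
    stop_config("decision column '", decision, "' not present in ", path)
  if (is.null(schema)) {
    cond <- setdiff(names(df), decision)
    kinds <- vapply(df[cond], infer_kind, character(1))
    schema <- hybrid_schema(cond, kinds, decision)
  }
  for (a in names(schema$kinds)) {
    if (!a %in% names(df))
      stop_config("schema attribute '", a, "' not present in ", path)
    if (schema$kinds[[a]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[a]]))
      bad <- which(!is.na(df[[a]]) & is.na(v))
      if (length(bad))
        stop_parse("column '", a, "' declared numeric but row ", bad[1],
                   " holds '", df[[a]][bad[1]], "'")
      df[[a]] <- v
    }
  }
  apply_missing_policy(hybrid_table(df, schema))
}

infer_kind <- function(cells) {
  obs <- cells[!is.na(cells)]
  if (!length(obs)) return("categorical")
  parsed <- suppressWarnings(as.numeric(obs))
  if (any(is.na(parsed))) "categorical" else "numeric"
}

#' Write a hybrid decision table to CSV
#'
#' Numeric cells are written with 17 significant digits so that reading the
#' file back reproduces every double exactly (round-trip identity).
#'
#' @param table a `"hybrid_table"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hybrid_csv <- function(table, path) {
  if (!inherits(table, "hybrid_table")) stop_contract("'table' must be a hybrid_table")
  df <- table$data
  for (a in names(df)) {
    if (is.double(df[[a]])) df[[a]] <- formatC(df[[a]], digits = 17, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "?")
  invisible(path)
}
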