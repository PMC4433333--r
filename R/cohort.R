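# Cohort container and CSV/JSON input-output.
#
# A cohort is a complete-case patient x feature table with a binary outcome
# (1 = died within 30 days post-discharge, 0 = survived) and optional
# severity-of-illness score columns consumed as plain numbers. Each row is
# one ICU admission treated as an independent "patient"; no de-duplication
# is attempted, so clinically similar admissions match on their data alone.

MISSING_SENTINELS <- c("", "na", "nan")

#' Declare the columns of a patient cohort
#'
#' A schema names the patient-id column, the binary outcome column, optional
#' numeric benchmark-score columns, and the predictor features, each tagged
#' as `"continuous"` or `"categorical"`.
#'
#' @param features Named character vector (or list) mapping feature name to
#'   kind, one of `"continuous"` or `"categorical"`.
#' @param outcome_column Name of the 0/1 outcome column.
#' @param score_columns Character vector of benchmark score columns (may be
#'   empty).
#' @param id_column Name of the unique patient-id column.
#' @return An object of class `cohort_schema`.
#' @examples
#' cohort_schema(c(age = "continuous", gender = "categorical"),
#'               outcome_column = "died30", id_column = "patient_id")
#' @export
cohort_schema <- function(features, outcome_column, score_columns = character(),
                          id_column = "patient_id") {
  features <- unlist(features)
  if (length(features) < 1L) abort("a schema needs at least one feature")
  if (is.null(names(features)) || any(!nzchar(names(features)))) {
    abort("'features' must be a named vector: name -> kind")
  }
  bad <- setdiff(unique(features), c("continuous", "categorical"))
  if (length(bad)) {
    abort("unknown feature kind(s): %s", paste(bad, collapse = ", "))
  }
  score_columns <- as.character(score_columns)
  all_cols <- c(id_column, outcome_column, score_columns, names(features))
  dup <- unique(all_cols[duplicated(all_cols)])
  if (length(dup)) {
    abort("column name(s) used more than once in schema: %s",
          paste(dup, collapse = ", "))
  }
  structure(
    list(features = features, outcome_column = outcome_column,
         score_columns = score_columns, id_column = id_column),
    class = "cohort_schema"
  )
}

schema_columns <- function(schema) {
  c(schema$id_column, names(schema$features), schema$outcome_column,
    schema$score_columns)
}

continuous_features <- function(schema) {
  names(schema$features)[schema$features == "continuous"]
}

categorical_features <- function(schema) {
  names(schema$features)[schema$features == "categorical"]
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat(sprintf(
    "cohort schema: %d features (%d continuous, %d categorical)\n",
    length(x$features), length(continuous_features(x)),
    length(categorical_features(x))
  ))
  cat(sprintf("  id: %s | outcome: %s | scores: %s\n", x$id_column,
              x$outcome_column,
              if (length(x$score_columns)) {
                paste(x$score_columns, collapse = ", ")
              } else "(none)"))
  invisible(x)
}

#' Read or write a cohort schema as JSON
#'
#' The on-disk form is a JSON document with keys `id_column`,
#' `outcome_column`, `score_columns` and `features` (array of
#' `{name, kind}` objects).
#'
#' @param path Path of the JSON schema file.
#' @return `read_cohort_schema()` returns a `cohort_schema`.
#' @export
read_cohort_schema <- function(path) {
  if (!file.exists(path)) abort("schema file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (key in c("id_column", "outcome_column", "features")) {
    if (is.null(doc[[key]])) abort("schema file is missing key '%s'", key)
  }
  feats <- doc$features
  if (is.data.frame(feats)) {
    features <- stats::setNames(as.character(feats$kind),
                                as.character(feats$name))
  } else {
    features <- vapply(feats, function(f) as.character(f$kind), character(1),
                       USE.NAMES = FALSE)
    names(features) <- vapply(feats, function(f) as.character(f$name),
                              character(1), USE.NAMES = FALSE)
  }
  cohort_schema(features, outcome_column = doc$outcome_column,
                score_columns = as.character(doc$score_columns %||% character()),
                id_column = doc$id_column)
}

#' @rdname read_cohort_schema
#' @param schema A `cohort_schema`.
#' @export
write_cohort_schema <- function(schema, path) {
  stopifnot(inherits(schema, "cohort_schema"))
  doc <- list(
    id_column = jsonlite::unbox(schema$id_column),
    outcome_column = jsonlite::unbox(schema$outcome_column),
    score_columns = as.character(schema$score_columns),
    features = data.frame(name = names(schema$features),
                          kind = unname(schema$features),
                          stringsAsFactors = FALSE)
  )
  jsonlite::write_json(doc, path, pretty = TRUE)
  invisible(path)
}

#' Construct a cohort from an in-memory data frame
#'
#' Validates a patient table against a schema and returns the canonical
#' in-memory cohort: complete cases only, outcome coerced to integer 0/1,
#' rows sorted by patient id so all downstream tie-breaking is
#' reproducible.
#'
#' @param data A data frame containing every column the schema declares.
#' @param schema A [cohort_schema()].
#' @param drop_incomplete Drop rows with missing declared values (with a
#'   warning) instead of erroring. Default `TRUE`.
#' @return An object of class `cohort`: a list with elements `data`
#'   (the validated data frame) and `schema`.
#' @export
new_cohort <- function(data, schema, drop_incomplete = TRUE) {
  stopifnot(inherits(schema, "cohort_schema"))
  cols <- schema_columns(schema)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort("schema column(s) absent from table: %s",
          paste(missing_cols, collapse = ", "))
  }
  data <- data[, cols, drop = FALSE]
  data[[schema$id_column]] <- as.character(data[[schema$id_column]])
  for (f in categorical_features(schema)) data[[f]] <- as.character(data[[f]])

  # complete-case rule: blank / NA / NaN strings count as missing
  is_missing <- function(col) {
    if (is.character(col)) {
      is.na(col) | tolower(trimws(col)) %in% MISSING_SENTINELS
    } else {
      is.na(col)
    }
  }
  miss <- Reduce(`|`, lapply(data, is_missing))
  if (any(miss)) {
    if (!drop_incomplete) abort("%d row(s) have missing declared values",
                                sum(miss))
    warn("dropped %d row(s) with missing values (complete-case rule)",
         sum(miss))
    data <- data[!miss, , drop = FALSE]
  }
  if (nrow(data) == 0L) abort("cohort is empty after complete-case filtering")

  ids <- data[[schema$id_column]]
  if (anyDuplicated(ids)) {
    abort("duplicate patient id(s): %s",
          paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }

  for (f in continuous_features(schema)) {
    v <- suppressWarnings(as.numeric(data[[f]]))
    if (anyNA(v)) {
      abort("feature '%s' has non-numeric value(s), e.g. at id %s", f,
            ids[which(is.na(v))[1]])
    }
    data[[f]] <- v
  }
  for (s in schema$score_columns) {
    v <- suppressWarnings(as.numeric(data[[s]]))
    if (anyNA(v)) {
      abort("score column '%s' has non-numeric value(s), e.g. at id %s", s,
            ids[which(is.na(v))[1]])
    }
    data[[s]] <- v
  }
  y_raw <- data[[schema$outcome_column]]
  y <- suppressWarnings(as.numeric(y_raw))
  bad <- is.na(y) | !(y %in% c(0, 1))
  if (any(bad)) {
    abort("outcome column '%s' must be 0 or 1; offending id %s has value '%s'",
          schema$outcome_column, ids[which(bad)[1]], y_raw[which(bad)[1]])
  }
  data[[schema$outcome_column]] <- as.integer(y)

  data <- data[order(data[[schema$id_column]], method = "radix"), ,
               drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, schema = schema), class = "cohort")
}

#' Load a cohort from a CSV table and a JSON schema
#'
#' Reads a comma-delimited UTF-8 table with a header row, validates it
#' against the schema, applies the complete-case rule (rows with any
#' missing declared value are dropped with a warning giving the count),
#' and returns the cohort sorted by patient id.
#'
#' @param table_path Path of the cohort CSV.
#' @param schema_path Path of the JSON schema sidecar.
#' @return A `cohort`.
#' @seealso [write_cohort()], [new_cohort()]
#' @export
load_cohort <- function(table_path, schema_path) {
  schema <- read_cohort_schema(schema_path)
  if (!file.exists(table_path)) abort("cohort table not found: %s", table_path)
  raw <- utils::read.csv(table_path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  new_cohort(raw, schema)
}

#' Write a cohort back to CSV + JSON schema
#'
#' Round-trip safe: `load_cohort()` applied to the written files
#' reconstructs the cohort field-for-field (categorical level strings are
#' preserved exactly; numbers are written with full precision).
#'
#' @param cohort A `cohort`.
#' @param table_path Output CSV path.
#' @param schema_path Output JSON schema path.
#' @export
write_cohort <- function(cohort, table_path, schema_path) {
  stopifnot(inherits(cohort, "cohort"))
  out <- cohort$data
  num_cols <- vapply(out, is.double, logical(1))
  for (j in which(num_cols)) out[[j]] <- format(out[[j]], digits = 17,
                                                trim = TRUE, scientific = FALSE)
  utils::write.csv(out, table_path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  write_cohort_schema(cohort$schema, schema_path)
  invisible(cohort)
}

#' @export
print.cohort <- function(x, ...) {
  y <- outcomes(x)
  cat(sprintf("cohort: %d patients, %d features, outcome prevalence %.3f\n",
              nrow(x$data), length(x$schema$features), mean(y)))
  print(x$schema)
  invisible(x)
}

# ---- accessors -------------------------------------------------------------

#' Cohort accessors
#'
#' @param cohort A `cohort`.
#' @return `patient_ids()` the character id vector (sorted); `outcomes()`
#'   the integer 0/1 outcome vector; `cohort_scores()` the numeric score
#'   matrix (possibly 0 columns); `n_patients()` the row count.
#' @export
patient_ids <- function(cohort) cohort$data[[cohort$schema$id_column]]

#' @rdname patient_ids
#' @export
outcomes <- function(cohort) cohort$data[[cohort$schema$outcome_column]]

#' @rdname patient_ids
#' @export
cohort_scores <- function(cohort) {
  as.matrix(cohort$data[, cohort$schema$score_columns, drop = FALSE])
}

#' @rdname patient_ids
#' @export
n_patients <- function(cohort) nrow(cohort$data)

#' Subset the patients of a cohort
#'
#' @param cohort A `cohort`.
#' @param idx Logical or integer row index.
#' @return A `cohort` with the selected patients, in the selected order.
#' @export
cohort_subset <- function(cohort, idx) {
  out <- cohort
  out$data <- cohort$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}
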