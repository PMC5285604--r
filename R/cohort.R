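#' Construct a validated cohort table
#'
#' A `cohort_table` is a data.frame whose columns follow the schema order
#' (categorical/binary columns stored as factors with the declared levels),
#' plus the integer outcome column `death_30d`. Rows are complete cases:
#' records with any missing value are rejected at construction, mirroring
#' the complete-case inclusion rule applied to the source cohort.
#'
#' @param data data.frame with one row per ICU admission.
#' @param schema a `feature_schema`.
#' @return A `cohort_table`; attribute `n_excluded` counts rows dropped for
#'   missingness, attribute `patient_index` holds stable 1-based ids.
#' @export
cohort_table <- function(data, schema) {
  stopifnot(inherits(schema, "feature_schema"), is.data.frame(data))
  cols <- c(schema$entries$name, "death_30d")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(data), cols)
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  data <- data[, cols, drop = FALSE]

  for (i in seq_len(nrow(schema$entries))) {
    nm <- schema$entries$name[i]
    if (schema$entries$kind[i] == "numeric") {
      v <- data[[nm]]
      if (is.character(v)) {
        v[!nzchar(trimws(v))] <- NA
        vn <- suppressWarnings(as.numeric(v))
        if (any(!is.na(v) & is.na(vn)))
          stop("non-numeric value in column '", nm, "'")
        v <- vn
      }
      if (any(is.infinite(v), na.rm = TRUE))
        stop("non-finite value in column '", nm, "'")
      data[[nm]] <- as.numeric(v)
    } else {
      lv <- schema$levels[[nm]]
      v <- as.character(data[[nm]])
      v[!is.na(v) & !nzchar(trimws(v))] <- NA
      bad <- setdiff(unique(v[!is.na(v)]), lv)
      if (length(bad))
        stop("unknown level(s) in column '", nm, "': ",
             paste(bad, collapse = ", "))
      data[[nm]] <- factor(v, levels = lv)
    }
  }
  y <- data$death_30d
  if (is.character(y)) {
    y[!nzchar(trimws(y))] <- NA
    y <- suppressWarnings(as.numeric(y))
  }
  if (any(!is.na(y) & !(y %in% c(0, 1))))
    stop("outcome 'death_30d' must be 0 or 1")
  data$death_30d <- as.integer(y)

  keep <- stats::complete.cases(data)
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message("cohort_table: excluded ", n_excluded, " row(s) with missing data")
  data <- data[keep, , drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            schema = schema,
            patient_index = seq_len(nrow(data)),
            n_excluded = n_excluded,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x), " patients, ",
      n_predictors(attr(x, "schema")), " predictors, ",
      sum(x$death_30d), " deaths (",
      sprintf("%.2f%%", 100 * mean(x$death_30d)), ")\n", sep = "")
  invisible(x)
}

#' Schema attached to a cohort
#' @param cohort a `cohort_table`.
#' @return The `feature_schema` the cohort was validated against.
#' @export
cohort_schema <- function(cohort) attr(cohort, "schema")

#' Predictor columns of a cohort (outcome dropped)
#' @param cohort a `cohort_table`.
#' @return data.frame of the predictor columns in schema order.
#' @export
cohort_features <- function(cohort) {
  sch <- cohort_schema(cohort)
  as.data.frame(cohort)[, sch$entries$name, drop = FALSE]
}

#' Read a cohort from CSV
#'
#' Expects a header row matching the schema's predictor names plus the
#' outcome column `death_30d`. Rows with any missing cell are excluded and
#' counted (complete-case rule); unknown columns, non-coercible values and
#' undeclared categorical levels fail with a descriptive error.
#'
#' @param path CSV file path (UTF-8, "." decimal).
#' @param schema a `feature_schema`.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, schema) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("NA", ""))
  cohort_table(raw, schema)
}

#' Write a cohort to CSV
#'
#' Columns are written in schema order with the outcome last; categorical
#' levels are written verbatim, so `read_cohort(write_cohort(x))` is the
#' identity on valid cohorts.
#'
#' @param cohort a `cohort_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- as.data.frame(cohort)
  for (nm in names(out)) if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-hot encode predictor columns
#'
#' Numeric predictors pass through; binary/categorical predictors become
#' 0/1 indicator columns for every level after the first declared level
#' (reference coding). Encoding happens at model-training time only - the
#' cohort itself always stores level strings.
#'
#' @param data a `cohort_table` or a data.frame of predictor columns.
#' @param schema a `feature_schema`; defaults to the cohort's own schema.
#' @return Numeric matrix with one row per patient.
#' @export
encode_features <- function(data, schema = NULL) {
  if (inherits(data, "cohort_table")) {
    if (is.null(schema)) schema <- cohort_schema(data)
    data <- cohort_features(data)
  }
  stopifnot(inherits(schema, "feature_schema"))
  cols <- list()
  for (i in seq_len(nrow(schema$entries))) {
    nm <- schema$entries$name[i]
    if (schema$entries$kind[i] == "numeric") {
      cols[[nm]] <- as.numeric(data[[nm]])
    } else {
      lv <- schema$levels[[nm]]
      v <- as.character(data[[nm]])
      for (l in lv[-1])
        cols[[paste0(nm, "=", l)]] <- as.numeric(v == l)
    }
  }
  do.call(cbind, cols)
}
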