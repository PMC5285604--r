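#' Feature schema for an ICU admission cohort
#'
#' A `feature_schema` describes, in order, the predictor variables of a
#' cohort table: name, kind (`numeric`, `binary` or `categorical`), declared
#' levels for the non-numeric kinds, measurement unit and variable group.
#' The fixed binary outcome column is named `death_30d` (1 = death within 30
#' days of ICU admission).
#'
#' @param entries data.frame with columns `name`, `kind`, `unit`, `group`.
#' @param levels named list mapping each binary/categorical name to its
#'   declared level strings (first level is the reference at encoding time).
#' @return An object of class `feature_schema`.
#' @export
feature_schema <- function(entries, levels = list()) {
  stopifnot(is.data.frame(entries),
            all(c("name", "kind", "unit", "group") %in% names(entries)))
  entries <- entries[, c("name", "kind", "unit", "group")]
  entries[] <- lapply(entries, as.character)
  if (anyDuplicated(entries$name))
    stop("duplicate feature names: ",
         paste(unique(entries$name[duplicated(entries$name)]), collapse = ", "))
  bad <- setdiff(entries$kind, c("numeric", "binary", "categorical"))
  if (length(bad)) stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  need_lev <- entries$name[entries$kind != "numeric"]
  miss <- setdiff(need_lev, names(levels))
  if (length(miss)) stop("missing level declarations for: ", paste(miss, collapse = ", "))
  for (nm in need_lev) {
    lv <- levels[[nm]]
    if (length(lv) < 2 || anyDuplicated(lv))
      stop("feature '", nm, "' needs >= 2 distinct levels")
    if (entries$kind[entries$name == nm] == "binary" && length(lv) != 2)
      stop("binary feature '", nm, "' must have exactly 2 levels")
  }
  structure(list(entries = entries, levels = levels[need_lev]),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", nrow(x$entries), " predictors\n", sep = "")
  print(table(factor(x$entries$group,
                     levels = unique(x$entries$group))))
  invisible(x)
}

#' Number of predictors in a schema
#' @param schema a `feature_schema`.
#' @return Integer count of predictor entries.
#' @export
n_predictors <- function(schema) nrow(schema$entries)

vital_signals <- function() {
  data.frame(
    name = c("hr", "map", "sbp", "spo2", "resp_rate", "temp"),
    unit = c("bpm", "mmHg", "mmHg", "%", "breaths/min", "degC"),
    stringsAsFactors = FALSE
  )
}

lab_signals <- function() {
  data.frame(
    name = c("hematocrit", "wbc", "glucose", "hco3",
             "potassium", "sodium", "bun", "creatinine"),
    unit = c("%", "10^9/L", "mg/dL", "mEq/L",
             "mEq/L", "mEq/L", "mg/dL", "mg/dL"),
    stringsAsFactors = FALSE
  )
}

#' Build the 75-predictor ICU admission schema
#'
#' The first-24-hour feature set used throughout the package: demographics
#' (age, gender), administrative variables (admission type, ICU service
#' type), six vital signs summarized as min and max in each of the four
#' 6-hour windows of the first ICU day (48 variables), eight labs as
#' first-day min and max (16), two intervention flags (vasopressor therapy;
#' mechanical ventilation or CPAP), the worst Glasgow Coma Scale score, and
#' total urinary output per 6-hour window (4) - 75 predictors in total.
#'
#' @return A `feature_schema` with exactly 75 predictor entries.
#' @examples
#' sch <- make_table1_schema()
#' n_predictors(sch)  # 75
#' @export
make_table1_schema <- function() {
  rows <- list()
  lev <- list()
  add <- function(name, kind, unit, group) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, kind = kind, unit = unit, group = group,
      stringsAsFactors = FALSE)
  }
  add("age", "numeric", "years", "demographics")
  add("gender", "binary", "", "demographics")
  lev$gender <- c("female", "male")
  add("admission_type", "categorical", "", "administrative")
  lev$admission_type <- c("elective", "urgent", "emergency")
  add("icu_service_type", "categorical", "", "administrative")
  lev$icu_service_type <- c("MICU", "SICU", "CCU", "CSRU")
  vs <- vital_signals()
  for (i in seq_len(nrow(vs)))
    for (w in 1:4)
      for (st in c("min", "max"))
        add(sprintf("%s_%s_w%d", vs$name[i], st, w), "numeric", vs$unit[i], "vitals")
  lb <- lab_signals()
  for (i in seq_len(nrow(lb)))
    for (st in c("min", "max"))
      add(sprintf("%s_%s", lb$name[i], st), "numeric", lb$unit[i], "labs")
  for (nm in c("vasopressor", "mech_vent_cpap")) {
    add(nm, "binary", "", "intervention")
    lev[[nm]] <- c("no", "yes")
  }
  add("gcs_worst", "numeric", "score", "other")
  for (w in 1:4) add(sprintf("urine_w%d", w), "numeric", "mL", "other")
  feature_schema(do.call(rbind, rows), lev)
}

#' Serialize a schema to JSON
#' @param schema a `feature_schema`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
schema_to_json <- function(schema, path = NULL) {
  doc <- lapply(seq_len(nrow(schema$entries)), function(i) {
    e <- as.list(schema$entries[i, ])
    if (e$kind != "numeric") e$levels <- schema$levels[[e$name]]
    e
  })
  js <- jsonlite::toJSON(list(outcome = "death_30d", predictors = doc),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(js)) stop("serialization failed")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a schema back from JSON
#' @param path file written by [schema_to_json()].
#' @return A `feature_schema`.
#' @export
schema_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- do.call(rbind, lapply(doc$predictors, function(e)
    data.frame(name = e$name, kind = e$kind, unit = e$unit, group = e$group,
               stringsAsFactors = FALSE)))
  levels <- list()
  for (e in doc$predictors)
    if (!is.null(e$levels)) levels[[e$name]] <- unlist(e$levels)
  feature_schema(entries, levels)
}
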