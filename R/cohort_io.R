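# Cohort ingestion: ADNIMERGE-dialect CSV -> filtered, encoded, complete-case
# assessment table.

#' The fourteen features retained after cohort filtering
#'
#' Demographics (age, gender, marital status) plus eleven neuropsychological
#' assessment scores: CDR sum of boxes, ADAS-Cog 11/13 and its memory item,
#' MMSE, the three RAVLT subscores, delayed logical-memory total, trail-making
#' time and the Functional Activities Questionnaire.
#'
#' @return Character vector of the fourteen feature names.
#' @export
table4_features <- function() {
  c("AGE", "PTGENDER", "PTMARRY", "CDRSB", "ADAS11", "ADAS13", "ADASQ4",
    "MMSE", "RAVLT.immediate", "RAVLT.learning", "RAVLT.forgetting",
    "LDELTOTAL", "TRABSCOR", "FAQ")
}

#' Nominal encodings for the qualitative cohort variables
#'
#' Diagnosis: CN = 0, SMC = 1, EMCI = 2, LMCI = 3, AD = 4 ("NC" is accepted
#' as a synonym of CN). Gender: Female = 0, Male = 1. Marital status:
#' Never married = 0, Married = 1, Divorced = 2, Widowed = 3.
#'
#' @return Named list of named integer vectors (`diagnosis`, `gender`,
#'   `marry`), each mapping category label to code.
#' @export
nominal_codes <- function() {
  list(
    diagnosis = c(CN = 0L, SMC = 1L, EMCI = 2L, LMCI = 3L, AD = 4L),
    gender = c(Female = 0L, Male = 1L),
    marry = c("Never married" = 0L, "Married" = 1L, "Divorced" = 2L,
              "Widowed" = 3L)
  )
}

# label synonyms tolerated on input (dialect drift across releases)
label_aliases <- list(
  diagnosis = c(NC = "CN"),
  marry = c(Nevermarried = "Never married")
)

#' Cohort filtering options
#'
#' @param age_min,age_max Closed age interval retained at enrolment (years).
#' @param ethnicity_pattern Case-insensitive regular expression a PTETHCAT
#'   value must match to be retained; the default matches any value
#'   *starting with* "Hisp" to absorb dialect drift ("Hisp/Latino",
#'   "Hispanic/Latino", ...) while excluding "Not Hisp/Latino".
#' @param missing_markers Strings normalized to the missing marker on read.
#'   ADNI's "-4" code is deliberately not treated as missing by default.
#' @param column_aliases Named character vector mapping alternate column
#'   names to canonical ones (e.g. `DX_bl` to `DX.bl`).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(age_min = 53, age_max = 95,
                          ethnicity_pattern = "^Hisp",
                          missing_markers = c("", "NA", "N/A"),
                          column_aliases = c(DX_bl = "DX.bl")) {
  stopifnot(age_min <= age_max)
  structure(list(age_min = age_min, age_max = age_max,
                 ethnicity_pattern = ethnicity_pattern,
                 missing_markers = missing_markers,
                 column_aliases = column_aliases),
            class = "cohort_config")
}

#' Read an ADNIMERGE-dialect CSV
#'
#' Reads all rows and columns verbatim, normalizes the configured missing
#' markers to `NA`, parses numeric columns where parseable and keeps the
#' rest as text. Column aliases are renamed to their canonical form.
#'
#' @param path Path to a comma-separated file with a header row.
#' @param config A [cohort_config()].
#' @return A `data.frame` of class `raw_cohort`.
#' @export
read_cohort <- function(path, config = cohort_config()) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path)
  raw <- utils::read.csv(path, na.strings = config$missing_markers,
                         check.names = FALSE, stringsAsFactors = FALSE)
  as_raw_cohort(raw, config)
}

#' Treat an in-memory data frame as a raw cohort
#'
#' @param df A data frame in the ADNIMERGE dialect.
#' @param config A [cohort_config()] (used for column aliases).
#' @return A `data.frame` of class `raw_cohort`.
#' @export
as_raw_cohort <- function(df, config = cohort_config()) {
  nm <- names(df)
  if (anyDuplicated(nm)) {
    stop("duplicate column names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  hit <- nm %in% names(config$column_aliases)
  nm[hit] <- config$column_aliases[nm[hit]]
  names(df) <- nm
  class(df) <- c("raw_cohort", "data.frame")
  df
}

required_columns <- function() {
  c("VISCODE", "AGE", "PTETHCAT", "DX.bl", table4_features())
}

#' Apply the cohort inclusion criteria
#'
#' Filters rows in a fixed order: (1) drop rows with a missing visit code,
#' then drop the VISCODE column; (2) keep ages inside the closed interval
#' `[age_min, age_max]`; (3) keep rows whose ethnicity matches the
#' Hispanic/Latino pattern, then drop PTETHCAT; (4) prune all columns except
#' the fourteen retained features and the diagnosis. Complete-case removal
#' is *not* applied here (see [encode_and_complete()]); the returned report
#' counts the rows each criterion removed.
#'
#' @param raw A `raw_cohort`.
#' @param config A [cohort_config()].
#' @return A list with `cohort` (filtered `raw_cohort`) and `report`
#'   (an `inclusion_report`: `n_input`, `n_after_criteria`, `n_final`,
#'   `dropped_columns`, `per_criterion_drops`).
#' @export
apply_inclusion_criteria <- function(raw, config = cohort_config()) {
  missing_cols <- setdiff(required_columns(), names(raw))
  if (length(missing_cols)) {
    stop("required column(s) missing from cohort: ",
         paste(missing_cols, collapse = ", "))
  }
  n_input <- nrow(raw)
  drops <- c(viscode = 0L, age = 0L, ethnicity = 0L, complete_case = NA)

  keep <- !is.na(raw$VISCODE)
  drops["viscode"] <- sum(!keep)
  df <- raw[keep, setdiff(names(raw), "VISCODE"), drop = FALSE]

  age <- suppressWarnings(as.numeric(df$AGE))
  keep <- !is.na(age) & age >= config$age_min & age <= config$age_max
  drops["age"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  keep <- !is.na(df$PTETHCAT) &
    grepl(config$ethnicity_pattern, df$PTETHCAT, ignore.case = TRUE)
  drops["ethnicity"] <- sum(!keep)
  df <- df[keep, setdiff(names(df), "PTETHCAT"), drop = FALSE]

  wanted <- c(table4_features(), "DX.bl")
  dropped_columns <- setdiff(names(raw), c(wanted, "VISCODE", "PTETHCAT"))
  df <- df[, wanted, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("raw_cohort", "data.frame")

  report <- structure(
    list(n_input = n_input, n_after_criteria = nrow(df), n_final = NA_integer_,
         dropped_columns = dropped_columns, per_criterion_drops = drops),
    class = "inclusion_report")
  stopifnot(report$n_input - sum(drops[1:3]) == report$n_after_criteria)
  list(cohort = df, report = report)
}

encode_column <- function(values, codes, aliases, column) {
  v <- as.character(values)
  hit <- v %in% names(aliases)
  v[hit] <- aliases[v[hit]]
  unknown <- which(!is.na(v) & !(v %in% names(codes)))
  if (length(unknown)) {
    stop(sprintf("unknown %s label '%s' at row %d", column,
                 v[unknown[1]], unknown[1]))
  }
  out <- rep(NA_integer_, length(v))
  out[!is.na(v)] <- codes[v[!is.na(v)]]
  out
}

#' Decode a vector of diagnosis codes back to labels
#'
#' @param codes Integer codes in `0..4`.
#' @return Character labels (`CN`, `SMC`, `EMCI`, `LMCI`, `AD`).
#' @export
decode_diagnosis <- function(codes) {
  map <- nominal_codes()$diagnosis
  names(map)[match(codes, map)]
}

#' Encode qualitative variables and drop incomplete rows
#'
#' Maps diagnosis, gender and marital status to their nominal codes, then
#' removes every row containing any missing value (complete-case analysis).
#'
#' @param filtered A `raw_cohort` with the post-criteria schema (fourteen
#'   feature columns plus `DX.bl`), e.g. from [apply_inclusion_criteria()].
#' @param report Optionally the `inclusion_report` from the criteria step;
#'   its `n_final` and complete-case drop count are filled in.
#' @return A list with `cohort` (a [cohort_table()]) and `report`.
#' @export
encode_and_complete <- function(filtered, report = NULL) {
  wanted <- c(table4_features(), "DX.bl")
  missing_cols <- setdiff(wanted, names(filtered))
  if (length(missing_cols)) {
    stop("post-criteria schema incomplete, missing: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(filtered)[, wanted]
  codes <- nominal_codes()
  df$DX.bl <- encode_column(df$DX.bl, codes$diagnosis,
                            label_aliases$diagnosis, "diagnosis")
  df$PTGENDER <- encode_column(df$PTGENDER, codes$gender, c(), "gender")
  df$PTMARRY <- encode_column(df$PTMARRY, codes$marry,
                              label_aliases$marry, "marital status")
  for (col in table4_features()) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]

  cohort <- cohort_table(
    features = as.matrix(df[, table4_features(), drop = FALSE]),
    diagnosis = as.integer(df$DX.bl))

  if (is.null(report)) {
    report <- structure(
      list(n_input = nrow(filtered), n_after_criteria = nrow(filtered),
           n_final = NA_integer_, dropped_columns = character(),
           per_criterion_drops = c(viscode = 0L, age = 0L, ethnicity = 0L,
                                   complete_case = NA)),
      class = "inclusion_report")
  }
  report$per_criterion_drops["complete_case"] <- n_dropped
  report$n_final <- cohort$n
  list(cohort = cohort, report = report)
}

#' Construct a cohort table
#'
#' The complete-case subject-by-feature container used downstream: a numeric
#' feature matrix, the ordered feature names, and one diagnosis code per row.
#'
#' @param features Numeric matrix, subjects in rows.
#' @param diagnosis Integer codes, one per row.
#' @param labels Named integer vector mapping diagnosis label to code;
#'   defaults to the five phase-1 states.
#' @return A list of class `cohort_table` with fields `features`,
#'   `feature_names`, `diagnosis`, `labels`, `n`.
#' @export
cohort_table <- function(features, diagnosis,
                         labels = nominal_codes()$diagnosis) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) != length(diagnosis)) {
    stop("features and diagnosis length mismatch")
  }
  if (anyNA(features) || anyNA(diagnosis)) {
    stop("cohort table must be complete-case (no missing values)")
  }
  if (!all(diagnosis %in% labels)) {
    stop("diagnosis codes outside the declared label set")
  }
  structure(list(features = features, feature_names = colnames(features),
                 diagnosis = as.integer(diagnosis), labels = labels,
                 n = nrow(features)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  tab <- table(factor(x$diagnosis, levels = x$labels,
                      labels = names(x$labels)))
  cat(sprintf("<cohort_table> %d subjects x %d features\n",
              x$n, length(x$feature_names)))
  print(tab)
  invisible(x)
}

#' Write a cleaned cohort and its inclusion report to disk
#'
#' The cohort is written as CSV with the fourteen feature columns plus a
#' `DX` integer code; the report as JSON.
#'
#' @param cohort A `cohort_table`.
#' @param report An `inclusion_report` (or `NULL` to skip).
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_cohort <- function(cohort, csv_path, report = NULL, json_path = NULL) {
  df <- as.data.frame(cohort$features)
  df$DX <- cohort$diagnosis
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(report) && !is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(csv_path)
}
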