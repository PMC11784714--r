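# Confusion counts, the five evaluation metrics with explicit
# undefined-value semantics, per-group mean/SD summaries, and the published
# report layout.

#' Tally a 2x2 confusion table
#'
#' Class 1 is the positive (more-impaired) class.
#'
#' @param truth,predicted Equal-length 0/1 vectors.
#' @return A list of class `confusion_counts`: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (!all(c(truth, predicted) %in% 0:1)) stop("classes must be 0/1")
  structure(list(TP = sum(truth == 1 & predicted == 1),
                 TN = sum(truth == 0 & predicted == 0),
                 FP = sum(truth == 0 & predicted == 1),
                 FN = sum(truth == 1 & predicted == 0)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Sensitivity, specificity, precision, accuracy and F1 from counts
#'
#' Undefined-value semantics: a zero denominator yields `NA` (rendered "NA"
#' in reports); precision with `TP = 0` and `FP > 0` is a defined 0. F1, the
#' harmonic mean of precision and sensitivity, is `NA` whenever either is
#' `NA` or both are 0.
#'
#' @param counts A `confusion_counts`.
#' @param aggregation Label recorded in the report (`"pooled"` or
#'   `"fold-mean"`).
#' @return A list of class `metric_report` with the five metrics, `counts`
#'   and `aggregation`.
#' @export
compute_metrics <- function(counts, aggregation = "pooled") {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  sens <- safe_ratio(counts$TP, counts$TP + counts$FN)
  spec <- safe_ratio(counts$TN, counts$TN + counts$FP)
  prec <- safe_ratio(counts$TP, counts$TP + counts$FP)
  acc <- safe_ratio(counts$TP + counts$TN, n)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 accuracy = acc, f1 = f1, counts = counts,
                 aggregation = aggregation),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf(paste0("<metric_report> (%s) sens=%s spec=%s prec=%s ",
                     "acc=%s f1=%s\n"),
              x$aggregation, fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$precision), fmt(x$accuracy), fmt(x$f1)))
  invisible(x)
}

#' Per-group mean and SD of every feature
#'
#' @param cohort A `cohort_table`.
#' @param grouping Per-row group labels; defaults to the decoded diagnosis.
#' @return A data.frame of class `group_summary` with columns `group`,
#'   `feature`, `n`, `mean`, `sd` (sample SD, `NA` for groups of size < 2).
#' @export
summarize_groups <- function(cohort, grouping = NULL) {
  if (is.null(grouping)) {
    grouping <- names(cohort$labels)[match(cohort$diagnosis, cohort$labels)]
  }
  if (length(grouping) != cohort$n || anyNA(grouping)) {
    stop("every row must be mapped to a group")
  }
  out <- do.call(rbind, lapply(unique(grouping), function(g) {
    rows <- cohort$features[grouping == g, , drop = FALSE]
    data.frame(group = g, feature = colnames(rows), n = nrow(rows),
               mean = colMeans(rows),
               sd = if (nrow(rows) < 2) NA_real_ else apply(rows, 2,
                                                            stats::sd),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  class(out) <- c("group_summary", "data.frame")
  out
}

format_metric <- function(v) {
  if (is.null(v) || length(v) == 0) NULL
  else if (is.na(v)) "NA"
  else sprintf("%.4f", v)
}

#' Render metric reports in the published table layout
#'
#' One row per metric; per comparison, three columns (Orig / Syn / Custom)
#' holding the pooled metrics to four decimal places, with undefined values
#' rendered as "NA".
#'
#' @param results Named list: comparison name -> list with `original`,
#'   `synthetic`, `custom` `metric_report`s.
#' @param path Optional output path; extension `.md` writes a
#'   pipe-separated Markdown table, anything else CSV.
#' @return The rendered `data.frame` (metric rows, comparison/source
#'   columns), invisibly if written.
#' @export
render_report <- function(results, path = NULL) {
  if (!length(results)) stop("at least one comparison required")
  metrics <- c(Sensitivity = "sensitivity", Specificity = "specificity",
               Precision = "precision", Accuracy = "accuracy",
               `F1-score` = "f1")
  sources <- c(Orig = "original", Syn = "synthetic", Custom = "custom")
  out <- data.frame(Metric = names(metrics), stringsAsFactors = FALSE)
  for (comp in names(results)) {
    for (s in names(sources)) {
      rep <- results[[comp]][[sources[[s]]]]
      col <- vapply(metrics, function(m) {
        v <- format_metric(rep[[m]])
        if (is.null(v)) {
          stop("missing metric cell: ", comp, " / ", s, " / ", m)
        }
        v
      }, character(1))
      out[[paste(comp, s, sep = ".")]] <- unname(col)
    }
  }
  if (!is.null(path)) {
    if (grepl("\\.md$", path)) {
      lines <- c(paste0("| ", paste(names(out), collapse = " | "), " |"),
                 paste0("|", paste(rep("---", ncol(out)), collapse = "|"),
                        "|"),
                 apply(out, 1, function(r) {
                   paste0("| ", paste(r, collapse = " | "), " |")
                 }))
      writeLines(lines, path)
    } else {
      utils::write.csv(out, path, row.names = FALSE)
    }
    return(invisible(out))
  }
  out
}
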