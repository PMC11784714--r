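# Pairwise comparison datasets: ten phase-1 pairs over the five diagnostic
# states and three phase-2 pairs after regrouping (CN+SMC -> CN,
# EMCI+LMCI -> MCI, AD -> AD).

phase1_labels <- function() c("CN", "SMC", "EMCI", "LMCI", "AD")
phase2_labels <- function() c("CN", "MCI", "AD")

#' Construct a comparison specification
#'
#' @param phase 1 or 2.
#' @param group_a,group_b The two diagnosis labels; `group_b` is the
#'   more-impaired state and maps to class 1, so sensitivity downstream means
#'   detection of the more-impaired state.
#' @return A list of class `comparison_spec`.
#' @export
comparison_spec <- function(phase, group_a, group_b) {
  phase <- as.integer(phase)
  valid <- if (phase == 1L) phase1_labels() else phase2_labels()
  if (!phase %in% 1:2) stop("phase must be 1 or 2")
  if (!group_a %in% valid || !group_b %in% valid) {
    stop("labels for phase ", phase, " must be in {",
         paste(valid, collapse = ", "), "}")
  }
  if (identical(group_a, group_b)) stop("group_a and group_b must differ")
  structure(list(phase = phase, group_a = group_a, group_b = group_b),
            class = "comparison_spec")
}

#' Name a comparison, e.g. "CN_vs_AD_phase1"
#' @param spec A `comparison_spec`.
#' @return A single string.
#' @export
comparison_name <- function(spec) {
  sprintf("%s_vs_%s_phase%d", spec$group_a, spec$group_b, spec$phase)
}

#' Enumerate the thirteen pairwise comparisons
#'
#' The ten unordered phase-1 pairs over {CN, SMC, EMCI, LMCI, AD} followed by
#' the three phase-2 pairs over {CN, MCI, AD}, in the study's fixed order.
#'
#' @return A list of 13 `comparison_spec` objects.
#' @export
enumerate_comparisons <- function() {
  pairs <- list(
    c("CN", "SMC"), c("CN", "EMCI"), c("CN", "LMCI"), c("CN", "AD"),
    c("SMC", "EMCI"), c("SMC", "LMCI"), c("SMC", "AD"),
    c("EMCI", "LMCI"), c("EMCI", "AD"), c("LMCI", "AD"))
  specs <- lapply(pairs, function(p) comparison_spec(1L, p[1], p[2]))
  c(specs,
    list(comparison_spec(2L, "CN", "MCI"),
         comparison_spec(2L, "CN", "AD"),
         comparison_spec(2L, "MCI", "AD")))
}

#' Regroup diagnoses for phase 2
#'
#' CN and SMC merge into CN; EMCI and LMCI merge into MCI; AD is unchanged.
#' Feature values and row order are untouched. Idempotent: a phase-2 cohort
#' is returned as-is.
#'
#' @param cohort A `cohort_table`.
#' @return A `cohort_table` with labels {CN = 0, MCI = 1, AD = 2}.
#' @export
relabel_phase2 <- function(cohort) {
  p2 <- c(CN = 0L, MCI = 1L, AD = 2L)
  if (identical(cohort$labels, p2)) return(cohort)
  # phase-1 codes 0,1 -> CN; 2,3 -> MCI; 4 -> AD
  new_dx <- ifelse(cohort$diagnosis <= 1L, 0L,
                   ifelse(cohort$diagnosis <= 3L, 1L, 2L))
  cohort_table(cohort$features, new_dx, labels = p2)
}

#' Build one binary comparison dataset
#'
#' Selects the rows of the two groups and assigns label 0 to `group_a` and
#' label 1 to `group_b` (the more-impaired state). For a phase-2 spec the
#' cohort is regrouped first via [relabel_phase2()].
#'
#' @param cohort A `cohort_table`.
#' @param spec A `comparison_spec`.
#' @return A list of class `comparison_dataset` with fields `features`,
#'   `feature_names`, `label` (0/1), `spec`, `source`, `class_counts`.
#' @export
build_comparison <- function(cohort, spec) {
  if (spec$phase == 2L) cohort <- relabel_phase2(cohort)
  code_a <- cohort$labels[[spec$group_a]]
  code_b <- cohort$labels[[spec$group_b]]
  in_a <- cohort$diagnosis == code_a
  in_b <- cohort$diagnosis == code_b
  if (!any(in_a)) stop("empty class ", spec$group_a)
  if (!any(in_b)) stop("empty class ", spec$group_b)
  keep <- in_a | in_b
  comparison_dataset(
    features = cohort$features[keep, , drop = FALSE],
    label = as.integer(in_b[keep]),
    spec = spec, source = "original")
}

#' Construct a comparison dataset
#'
#' @param features Numeric matrix.
#' @param label Integer 0/1 vector, one per row.
#' @param spec A `comparison_spec`.
#' @param source One of `"original"`, `"synthetic"`, `"custom"`.
#' @return A list of class `comparison_dataset`.
#' @export
comparison_dataset <- function(features, label, spec,
                               source = c("original", "synthetic", "custom")) {
  source <- match.arg(source)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  label <- as.integer(label)
  if (nrow(features) != length(label)) stop("features/label length mismatch")
  if (!all(label %in% 0:1)) stop("labels must be 0/1")
  if (length(unique(label)) < 2L) stop("both classes must be present")
  structure(list(features = features, feature_names = colnames(features),
                 label = label, spec = spec, source = source,
                 class_counts = c(sum(label == 0L), sum(label == 1L))),
            class = "comparison_dataset")
}

#' Restrict a comparison dataset to a feature subset
#' @param data A `comparison_dataset`.
#' @param features Character vector of feature names to keep.
#' @return A `comparison_dataset` over those features only.
#' @export
subset_features <- function(data, features) {
  missing <- setdiff(features, data$feature_names)
  if (length(missing)) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  }
  comparison_dataset(data$features[, features, drop = FALSE], data$label,
                     data$spec, data$source)
}

#' @export
print.comparison_dataset <- function(x, ...) {
  cat(sprintf("<comparison_dataset> %s (%s): %d x %d [%s=%d, %s=%d]\n",
              comparison_name(x$spec), x$source, nrow(x$features),
              ncol(x$features), x$spec$group_a, x$class_counts[1],
              x$spec$group_b, x$class_counts[2]))
  invisible(x)
}

#' Write a comparison dataset as CSV
#'
#' Columns are the features plus a binary `label`; the file name follows
#' `<phase>_<A>_vs_<B>_<source>.csv`.
#'
#' @param data A `comparison_dataset`.
#' @param dir Output directory.
#' @return The file path, invisibly.
#' @export
write_comparison <- function(data, dir) {
  df <- as.data.frame(data$features)
  df$label <- data$label
  path <- file.path(dir, sprintf("%d_%s_vs_%s_%s.csv", data$spec$phase,
                                 data$spec$group_a, data$spec$group_b,
                                 data$source))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
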