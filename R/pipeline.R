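# End-to-end orchestration: ingest -> filter/encode -> 13 comparisons ->
# balanced augmentation -> feature selection on original and synthetic ->
# custom subset refinement -> ensemble evaluation -> reports and manifest.

#' Pipeline run configuration
#'
#' @param input_path Path to an ADNIMERGE-dialect CSV (alternatively pass a
#'   raw cohort directly to [run_pipeline()]).
#' @param seed Master seed; every random stage derives its own child seed
#'   from it, the stage name and the comparison name.
#' @param folds Cross-validation folds.
#' @param cohort_options A [cohort_config()].
#' @param augmentation Augmentation options as a list
#'   (`target_per_class`, `n_boost_rounds`, `perturbation_scale`); the seed
#'   is derived per comparison.
#' @param member_configs Five [member_config()]s.
#' @param out_dir Output directory for datasets, reports and the manifest;
#'   `NULL` keeps everything in memory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_path = NULL, seed, folds = 10,
                       cohort_options = cohort_config(),
                       augmentation = list(target_per_class = "balanced",
                                           n_boost_rounds = 50,
                                           perturbation_scale = 0.1),
                       member_configs = default_member_configs(),
                       out_dir = NULL) {
  if (missing(seed)) stop("run seed must be given explicitly")
  structure(list(input_path = input_path, seed = as.integer(seed),
                 folds = folds, cohort_options = cohort_options,
                 augmentation = augmentation,
                 member_configs = member_configs, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `input_path`, `seed`, `folds`, `out_dir`, an
#' `inclusion` block (`age_min`, `age_max`, `ethnicity_pattern`,
#' `missing_markers`, `column_aliases`) and an `augmentation` block
#' (`target_per_class`, `n_boost_rounds`, `perturbation_scale`).
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  y <- yaml::read_yaml(path)
  inc <- y$inclusion %||% list()
  co <- cohort_config(
    age_min = inc$age_min %||% 53, age_max = inc$age_max %||% 95,
    ethnicity_pattern = inc$ethnicity_pattern %||% "Hisp",
    missing_markers = unlist(inc$missing_markers %||% c("", "NA", "N/A")),
    column_aliases = unlist(inc$column_aliases %||% c(DX_bl = "DX.bl")))
  aug <- utils::modifyList(list(target_per_class = "balanced",
                                n_boost_rounds = 50,
                                perturbation_scale = 0.1),
                           y$augmentation %||% list())
  run_config(input_path = y$input_path, seed = y$seed,
             folds = y$folds %||% 10, cohort_options = co,
             augmentation = aug, out_dir = y$out_dir)
}

slim_trace <- function(trace) {
  it <- trace$iterations
  list(sizes = it$size, eliminated = it$eliminated, aic = it$aic,
       cv_accuracy = it$cv_accuracy, accepted = trace$accepted_set,
       stop_reason = trace$stop_reason)
}

run_one_comparison <- function(cohort, spec, cfg) {
  name <- comparison_name(spec)
  counts <- table(factor(
    relabel_if_needed(cohort, spec)$diagnosis,
    levels = relabel_if_needed(cohort, spec)$labels))
  original <- build_comparison(cohort, spec)
  if (any(original$class_counts < cfg$folds)) {
    stop(structure(class = c("cogstage_skip", "error", "condition"),
                   list(message = sprintf(
                     "class smaller than %d folds in %s", cfg$folds, name),
                     call = NULL)))
  }

  aug_cfg <- augmentation_config(
    target_per_class = cfg$augmentation$target_per_class,
    n_boost_rounds = cfg$augmentation$n_boost_rounds,
    perturbation_scale = cfg$augmentation$perturbation_scale,
    seed = derive_seed(cfg$seed, "augment", name))
  synthetic <- augment_adaboost(original, aug_cfg)

  sel_orig <- select_rfe_aic(original, cv_folds = cfg$folds,
                             seed = derive_seed(cfg$seed, "select-orig", name),
                             configs = cfg$member_configs)
  sel_syn <- select_rfe_aic(synthetic, cv_folds = cfg$folds,
                            seed = derive_seed(cfg$seed, "select-syn", name),
                            configs = cfg$member_configs)
  custom_set <- refine_custom_subset(original, sel_syn$accepted_set,
                                     greedy = length(sel_syn$accepted_set) > 12)

  eval_on <- function(data, features, tag) {
    cross_validate(subset_features(data, features), cfg$member_configs,
                   k = cfg$folds, seed = derive_seed(cfg$seed, "eval", tag,
                                                     name))
  }
  cv_orig <- eval_on(original, sel_orig$accepted_set, "orig")
  cv_syn <- eval_on(synthetic, sel_syn$accepted_set, "syn")
  cv_custom <- eval_on(original, custom_set, "custom")

  list(name = name, spec = spec,
       class_counts = list(original = original$class_counts,
                           synthetic = synthetic$class_counts),
       selected = list(original = sel_orig$accepted_set,
                       synthetic = sel_syn$accepted_set,
                       custom = custom_set),
       traces = list(original = slim_trace(sel_orig),
                     synthetic = slim_trace(sel_syn)),
       reports = list(original = cv_orig$report, synthetic = cv_syn$report,
                      custom = cv_custom$report),
       fold_means = list(original = cv_orig$fold_mean,
                         synthetic = cv_syn$fold_mean,
                         custom = cv_custom$fold_mean),
       datasets = list(original = original, synthetic = synthetic))
}

relabel_if_needed <- function(cohort, spec) {
  if (spec$phase == 2L) relabel_phase2(cohort) else cohort
}

#' Run the whole staged-classification pipeline
#'
#' Executes the six methodology stages: ingest the cohort, apply the
#' inclusion criteria and encoding, build the thirteen pairwise comparison
#' datasets, balance each by boosting-guided augmentation, select features
#' on the original and on the synthetic dataset, refine the custom subset by
#' exhaustive AIC minimisation on the original data, and evaluate the
#' Orig/Syn/Custom feature sets with the cross-validated hard-voting
#' ensemble. A comparison whose class is absent or smaller than the fold
#' count is skipped with an explicit reason. Every random step is seeded
#' from the master seed, so reruns with the same configuration reproduce all
#' numeric outputs exactly.
#'
#' @param cfg A [run_config()].
#' @param raw Optional in-memory `raw_cohort` (used instead of
#'   `cfg$input_path`).
#' @return A list of class `run_manifest`: `inclusion_report`,
#'   `comparisons` (one record or skip reason per spec), `config_hash`,
#'   `version`, plus the rendered metric table for the completed comparisons.
#' @export
run_pipeline <- function(cfg, raw = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(raw)) {
    if (is.null(cfg$input_path)) stop("either input_path or raw is required")
    raw <- read_cohort(cfg$input_path, cfg$cohort_options)
  } else {
    raw <- as_raw_cohort(as.data.frame(raw), cfg$cohort_options)
  }

  filtered <- apply_inclusion_criteria(raw, cfg$cohort_options)
  encoded <- encode_and_complete(filtered$cohort, filtered$report)
  cohort <- encoded$cohort

  records <- list()
  for (spec in enumerate_comparisons()) {
    name <- comparison_name(spec)
    rec <- tryCatch(
      run_one_comparison(cohort, spec, cfg),
      error = function(e) {
        msg <- conditionMessage(e)
        if (inherits(e, "cogstage_skip") ||
            grepl("^empty class|stratification error", msg)) {
          list(name = name, spec = spec, skipped = TRUE, reason = msg)
        } else {
          stop("pipeline failed at comparison ", name, ": ", msg,
               call. = FALSE)
        }
      })
    records[[name]] <- rec
  }

  complete <- Filter(function(r) is.null(r$skipped), records)
  metric_table <- if (length(complete)) {
    render_report(lapply(complete, `[[`, "reports"))
  } else {
    NULL
  }

  manifest <- structure(list(
    inclusion_report = encoded$report,
    comparisons = records,
    metric_table = metric_table,
    config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]),
    version = as.character(utils::packageVersion("cogstage")),
    seed = cfg$seed),
    class = "run_manifest")

  if (!is.null(cfg$out_dir)) write_manifest(manifest, cohort, cfg)
  manifest
}

write_manifest <- function(manifest, cohort, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(cfg$out_dir, "original_dataset.csv"),
               manifest$inclusion_report,
               file.path(cfg$out_dir, "inclusion_report.json"))
  for (rec in manifest$comparisons) {
    if (!is.null(rec$skipped)) next
    comp_dir <- file.path(cfg$out_dir, rec$name)
    dir.create(comp_dir, recursive = TRUE, showWarnings = FALSE)
    write_comparison(rec$datasets$original, comp_dir)
    write_comparison(rec$datasets$synthetic, comp_dir)
  }
  if (!is.null(manifest$metric_table)) {
    utils::write.csv(manifest$metric_table,
                     file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  json <- lapply(manifest$comparisons, function(rec) {
    if (!is.null(rec$skipped)) {
      return(list(name = rec$name, skipped = TRUE, reason = rec$reason))
    }
    list(name = rec$name,
         class_counts = rec$class_counts,
         selected = rec$selected,
         traces = rec$traces,
         metrics = lapply(rec$reports, function(r) {
           r[c("sensitivity", "specificity", "precision", "accuracy", "f1")]
         }),
         fold_means = rec$fold_means)
  })
  jsonlite::write_json(
    list(seed = manifest$seed, config_hash = manifest$config_hash,
         version = manifest$version,
         inclusion_report = unclass(manifest$inclusion_report),
         comparisons = json),
    file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(NULL)
}
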