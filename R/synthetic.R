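# Synthetic data: (a) boosting-guided augmentation that balances the two
# classes of a comparison dataset; (b) a fully artificial ADNIMERGE-like
# cohort generator so the pipeline is exercisable without access-controlled
# clinical data.

#' Augmentation options
#'
#' @param target_per_class `"balanced"` (grow every class to the current
#'   majority count) or an integer per-class target.
#' @param n_boost_rounds Boosting rounds for the stump ensemble whose final
#'   sample weights drive the sampling distribution.
#' @param perturbation_scale Jitter SD as a fraction of each class's
#'   per-feature SD.
#' @param seed Integer seed; mandatory, there is no silent default.
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(target_per_class = "balanced",
                                n_boost_rounds = 50,
                                perturbation_scale = 0.1,
                                seed) {
  if (missing(seed)) stop("augmentation seed must be given explicitly")
  if (!identical(target_per_class, "balanced")) {
    target_per_class <- as.integer(target_per_class)
    stopifnot(target_per_class >= 1L)
  }
  stopifnot(perturbation_scale >= 0, n_boost_rounds >= 1)
  structure(list(target_per_class = target_per_class,
                 n_boost_rounds = as.integer(n_boost_rounds),
                 perturbation_scale = perturbation_scale,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

# Adaptive boosting of decision stumps (SAMME weight updates). Only the final
# per-row sample weights are needed downstream: they concentrate on rows the
# stump ensemble finds hard to classify.
adaboost_weights <- function(x, y, n_rounds) {
  n <- nrow(x)
  df <- data.frame(.y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
  w <- rep(1 / n, n)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = -1, minsplit = 2, xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    miss <- pred != df$.y
    err <- sum(w[miss])
    if (err <= 0) break               # perfectly separated: weights settled
    if (err >= 0.5) break             # stump no better than chance
    alpha <- log((1 - err) / err)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  w
}

#' Balance a comparison dataset by boosting-guided augmentation
#'
#' Fits an adaptive-boosting ensemble of decision stumps on the dataset and
#' uses its final per-row sample weights, within each class, as the sampling
#' distribution for synthesis: new rows are drawn from existing rows with
#' probability proportional to their boosting weight (so synthesis
#' concentrates on hard-to-classify regions), then each feature is jittered
#' with zero-mean Gaussian noise of SD `perturbation_scale` times the class
#' SD and clipped to the class's observed range. Synthetic rows inherit
#' their source row's label; original rows are never modified.
#'
#' @param data A `comparison_dataset`.
#' @param cfg An [augmentation_config()].
#' @return A `comparison_dataset` with `source = "synthetic"` containing the
#'   original rows followed by the synthetic ones.
#' @export
augment_adaboost <- function(data, cfg) {
  stopifnot(inherits(data, "comparison_dataset"),
            inherits(cfg, "augmentation_config"))
  counts <- data$class_counts
  target <- if (identical(cfg$target_per_class, "balanced")) {
    max(counts)
  } else {
    if (cfg$target_per_class < max(counts)) {
      stop("target_per_class below an existing class count")
    }
    cfg$target_per_class
  }

  with_seed(cfg$seed, {
    w <- adaboost_weights(data$features, data$label, cfg$n_boost_rounds)
    new_rows <- list()
    new_labels <- integer()
    for (cls in 0:1) {
      idx <- which(data$label == cls)
      n_new <- target - length(idx)
      if (n_new <= 0) next
      if (length(idx) == 1L && cfg$perturbation_scale == 0) {
        warning("degenerate augmentation: single-row class with zero jitter ",
                "produces duplicates")
      }
      xc <- data$features[idx, , drop = FALSE]
      sds <- apply(xc, 2, stats::sd)
      sds[!is.finite(sds)] <- 0
      lo <- apply(xc, 2, min)
      hi <- apply(xc, 2, max)
      prob <- w[idx] / sum(w[idx])
      src <- sample(length(idx), n_new, replace = TRUE, prob = prob)
      noise <- matrix(stats::rnorm(n_new * ncol(xc)), n_new) *
        rep(cfg$perturbation_scale * sds, each = n_new)
      synth <- xc[src, , drop = FALSE] + noise
      synth <- pmin(pmax(synth, rep(lo, each = n_new)), rep(hi, each = n_new))
      new_rows[[length(new_rows) + 1L]] <- synth
      new_labels <- c(new_labels, rep(cls, n_new))
    }
    features <- rbind(data$features, do.call(rbind, new_rows))
    comparison_dataset(features, c(data$label, new_labels), data$spec,
                       source = "synthetic")
  })
}

# Instrument score ranges used to clip generated assessment values.
instrument_ranges <- function() {
  list(CDRSB = c(0, 18), ADAS11 = c(0, 70), ADAS13 = c(0, 85),
       ADASQ4 = c(0, 10), MMSE = c(0, 30), RAVLT.immediate = c(0, 75),
       RAVLT.learning = c(-5, 14), RAVLT.forgetting = c(-15, 15),
       LDELTOTAL = c(0, 25), TRABSCOR = c(0, 300), FAQ = c(0, 30))
}

assessment_features <- function() names(instrument_ranges())

# Per-diagnosis assessment means, ordered so scores worsen from CN to AD
# (MMSE, RAVLT immediate/learning and LDELTOTAL decrease; the rest increase).
default_group_means <- function() {
  m <- rbind(
    CDRSB            = c(0.03, 0.10, 1.3, 1.9, 4.6),
    ADAS11           = c(5.4, 6.0, 8.2, 10.6, 19.2),
    ADAS13           = c(8.4, 9.4, 13.2, 17.3, 29.6),
    ADASQ4           = c(2.6, 3.0, 4.6, 6.1, 8.4),
    MMSE             = c(29.1, 29.0, 28.0, 26.9, 23.2),
    RAVLT.immediate  = c(45.5, 44.0, 38.0, 31.8, 22.3),
    RAVLT.learning   = c(6.0, 5.6, 4.6, 3.5, 1.8),
    RAVLT.forgetting = c(3.5, 3.8, 4.4, 4.9, 5.4),
    LDELTOTAL        = c(13.6, 13.0, 9.1, 5.9, 1.8),
    TRABSCOR         = c(82, 86, 105, 131, 198),
    FAQ              = c(0.3, 0.7, 2.6, 4.8, 14.0))
  colnames(m) <- phase1_labels()
  m
}

default_group_sds <- function() {
  s <- rbind(
    CDRSB            = c(0.12, 0.30, 0.80, 1.00, 1.70),
    ADAS11           = c(2.8, 2.9, 3.4, 4.3, 6.5),
    ADAS13           = c(4.2, 4.3, 5.3, 6.4, 7.9),
    ADASQ4           = c(1.6, 1.7, 2.2, 2.3, 1.8),
    MMSE             = c(1.1, 1.2, 1.7, 1.8, 2.0),
    RAVLT.immediate  = c(9.9, 9.5, 10.5, 8.8, 7.2),
    RAVLT.learning   = c(2.3, 2.3, 2.5, 2.5, 1.8),
    RAVLT.forgetting = c(2.6, 2.7, 2.4, 2.4, 2.2),
    LDELTOTAL        = c(3.3, 3.4, 4.1, 3.3, 1.9),
    TRABSCOR         = c(38, 41, 52, 68, 82),
    FAQ              = c(0.7, 1.3, 2.9, 4.3, 3.0))
  colnames(s) <- phase1_labels()
  s
}

#' Specification of a synthetic ADNIMERGE-like cohort
#'
#' The defaults emulate the study cohort's scale and structure: five
#' diagnosis groups sized so that complete-case filtering leaves roughly 323
#' subjects with about 22 in the AD group, clinically realistic per-group
#' assessment means and SDs worsening from CN to AD (the FAQ distributions
#' separate CN from AD cleanly, as observed in the study cohort), and a
#' per-cell missing rate on the assessment columns calibrated to the study's
#' complete-case attrition (552 -> 323). Optional contaminating rows violate
#' exactly one inclusion criterion each (missing visit code, out-of-range
#' age, non-Hispanic ethnicity) so the ordered filter is exercised.
#'
#' @param n_per_group Named counts for CN, SMC, EMCI, LMCI, AD.
#' @param group_means,group_sds 11 x 5 matrices (assessment x group).
#' @param missing_rate Per-cell missing probability on assessment columns,
#'   in `[0, 1)`.
#' @param seed Integer seed (mandatory).
#' @param n_missing_viscode,n_age_out,n_non_hispanic Counts of contaminating
#'   rows appended after the in-criteria rows.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_per_group = c(CN = 136, SMC = 94, EMCI = 152,
                                         LMCI = 132, AD = 38),
                         group_means = default_group_means(),
                         group_sds = default_group_sds(),
                         missing_rate = 0.048,
                         seed,
                         n_missing_viscode = 25,
                         n_age_out = 50,
                         n_non_hispanic = 400) {
  if (missing(seed)) stop("fixture seed must be given explicitly")
  if (!all(names(n_per_group) %in% phase1_labels())) {
    stop("group labels must be within {",
         paste(phase1_labels(), collapse = ", "), "}")
  }
  stopifnot(all(group_sds >= 0), missing_rate >= 0, missing_rate < 1)
  structure(list(n_per_group = n_per_group, group_means = group_means,
                 group_sds = group_sds, missing_rate = missing_rate,
                 seed = as.integer(seed),
                 n_missing_viscode = n_missing_viscode,
                 n_age_out = n_age_out, n_non_hispanic = n_non_hispanic),
            class = "fixture_spec")
}

fixture_columns <- function() {
  c("VISCODE", "SITE", "COLPROT", "EXAMDATE", "AGE", "PTGENDER", "PTEDUCAT",
    "PTETHCAT", "PTRACCAT", "PTMARRY", "DX.bl", assessment_features())
}

# draw n subjects from one diagnosis group's distributions
draw_group_rows <- function(group, n, spec) {
  ranges <- instrument_ranges()
  scores <- sapply(assessment_features(), function(f) {
    v <- stats::rnorm(n, spec$group_means[f, group], spec$group_sds[f, group])
    pmin(pmax(v, ranges[[f]][1]), ranges[[f]][2])
  })
  if (n == 1L) scores <- matrix(scores, nrow = 1,
                                dimnames = list(NULL, assessment_features()))
  data.frame(
    VISCODE = rep("bl", n),
    SITE = sample(100:199, n, replace = TRUE),
    COLPROT = rep("ADNI3", n),
    EXAMDATE = rep("2023-10-15", n),
    AGE = round(stats::runif(n, 53, 95), 1),
    PTGENDER = sample(c("Female", "Male"), n, replace = TRUE),
    PTEDUCAT = sample(8:20, n, replace = TRUE),
    PTETHCAT = rep("Hisp/Latino", n),
    PTRACCAT = sample(c("White", "More than one", "Unknown"), n,
                      replace = TRUE),
    PTMARRY = sample(names(nominal_codes()$marry), n, replace = TRUE),
    DX.bl = rep(group, n),
    as.data.frame(scores),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Generate a synthetic ADNIMERGE-like raw cohort
#'
#' Assessment scores are drawn from per-group normal distributions clipped to
#' each instrument's range; age is uniform on the retained interval, gender
#' and marital status uniform over their category sets, ethnicity
#' Hispanic/Latino and visit code `"bl"` for in-criteria rows. Missing
#' markers are injected into assessment columns at `missing_rate`, and
#' contaminating rows (one violated criterion each) are appended per the
#' spec. Fully reproducible from the seed.
#'
#' @param spec A [fixture_spec()].
#' @return A `data.frame` of class `raw_cohort` in the ADNIMERGE dialect.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    groups <- names(spec$n_per_group)[spec$n_per_group > 0]
    parts <- lapply(groups, function(g) {
      draw_group_rows(g, spec$n_per_group[[g]], spec)
    })

    contaminate <- function(n, tweak) {
      if (n == 0) return(NULL)
      g <- sample(phase1_labels(), n, replace = TRUE)
      rows <- do.call(rbind, lapply(seq_len(n), function(i) {
        draw_group_rows(g[i], 1L, spec)
      }))
      tweak(rows)
    }
    parts <- c(parts, list(
      contaminate(spec$n_missing_viscode, function(r) {
        r$VISCODE <- NA_character_; r
      }),
      contaminate(spec$n_age_out, function(r) {
        n <- nrow(r)
        low <- stats::runif(n) < 0.5
        r$AGE <- ifelse(low, round(stats::runif(n, 40, 52.9), 1),
                        round(stats::runif(n, 95.1, 103), 1))
        r
      }),
      contaminate(spec$n_non_hispanic, function(r) {
        r$PTETHCAT <- sample(c("Not Hisp/Latino", "Unknown"), nrow(r),
                             replace = TRUE, prob = c(0.9, 0.1))
        r
      })))
    parts <- parts[!vapply(parts, is.null, logical(1))]

    df <- if (length(parts)) {
      do.call(rbind, parts)
    } else {
      empty <- lapply(fixture_columns(), function(x) character(0))
      names(empty) <- fixture_columns()
      for (f in c("AGE", assessment_features())) empty[[f]] <- numeric(0)
      as.data.frame(empty, check.names = FALSE)
    }

    if (spec$missing_rate > 0 && nrow(df) > 0) {
      for (f in assessment_features()) {
        hit <- stats::runif(nrow(df)) < spec$missing_rate
        df[[f]][hit] <- NA_real_
      }
    }
    rownames(df) <- NULL
    class(df) <- c("raw_cohort", "data.frame")
    df
  })
}
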