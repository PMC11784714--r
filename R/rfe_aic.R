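# Feature selection: recursive feature elimination with a joint
# AIC + cross-validated accuracy stopping rule, and an exhaustive
# AIC-minimising subset refiner.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

binomial_loglik <- function(y, eta) {
  # numerically safe binomial log-likelihood at linear predictor eta
  sum(ifelse(y == 1, -softplus(-eta), -softplus(eta)))
}

# Ridge-penalized logistic regression by Newton iterations on standardized
# features. Used as the stabilized fit when maximum likelihood separates
# perfectly, and as the L2-regularized ensemble member. The intercept is
# never penalized. Returns coefficients on the original feature scale.
ridge_logistic <- function(x, y, lambda = 1e-8, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  std <- standardize_fit(x)
  xs <- cbind(1, standardize_apply(x, std))
  p <- ncol(xs)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  penalized_ll <- function(b) {
    binomial_loglik(y, drop(xs %*% b)) - lambda / 2 * sum(b[-1]^2)
  }
  beta <- numeric(p)
  ll_old <- penalized_ll(beta)
  for (i in seq_len(max_iter)) {
    eta <- drop(xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    h <- crossprod(xs * w, xs) + pen
    g <- crossprod(xs, y - mu) - pen %*% beta
    step <- solve(h, g)
    ll <- penalized_ll(beta + step)
    halvings <- 0
    while ((is.na(ll) || ll < ll_old) && halvings < 30) {
      step <- step / 2
      ll <- penalized_ll(beta + step)
      halvings <- halvings + 1
    }
    if (is.na(ll) || ll < ll_old) break   # no ascent step found: converged
    beta <- beta + step
    if (ll - ll_old < tol) break
    ll_old <- ll
  }
  # map back to the raw feature scale
  b_raw <- beta[-1] / std$scale
  b0 <- beta[1] - sum(beta[-1] * std$center / std$scale)
  list(coef = c(`(Intercept)` = b0, stats::setNames(b_raw, colnames(x))),
       coef_std = stats::setNames(beta[-1], colnames(x)),
       log_likelihood = binomial_loglik(y, drop(xs %*% beta)))
}

# Maximum-likelihood logistic fit with separation detection; falls back to a
# tiny-ridge stabilized fit (lambda = 1e-8 on standardized features) when the
# ML fit separates, so that the likelihood stays finite and well defined.
logistic_fit <- function(x, y, stabilize_lambda = 1e-8) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!separated) {
    return(list(coef = stats::coef(fit),
                log_likelihood = as.numeric(stats::logLik(fit)),
                separated = FALSE))
  }
  rf <- ridge_logistic(x, y, lambda = stabilize_lambda)
  list(coef = rf$coef, log_likelihood = rf$log_likelihood, separated = TRUE)
}

#' Akaike information criterion of a logistic model on a feature subset
#'
#' Fits a maximum-likelihood logistic regression of the class label on the
#' given features and returns `AIC = 2k - 2 ln(L)` with
#' `k = |features| + 1` (intercept included) and `ln(L)` the maximized
#' binomial log-likelihood. Under perfect separation the fit is stabilized
#' with a tiny L2 penalty on standardized features and flagged.
#'
#' @param data A `comparison_dataset`.
#' @param features Non-empty character vector of feature names.
#' @return A list of class `aic_result`: `k`, `log_likelihood`, `aic`,
#'   `separated`.
#' @export
compute_aic <- function(data, features) {
  stopifnot(length(features) >= 1)
  sub <- subset_features(data, features)
  fit <- logistic_fit(sub$features, sub$label)
  k <- length(features) + 1L
  structure(list(k = k, log_likelihood = fit$log_likelihood,
                 aic = 2 * k - 2 * fit$log_likelihood,
                 separated = fit$separated),
            class = "aic_result")
}

#' Feature importance as absolute standardized logistic coefficients
#'
#' Standardizes the features to zero mean and unit SD, fits a logistic
#' regression on all of them, and scores each feature by the absolute value
#' of its standardized coefficient. Zero-variance features get importance 0.
#' Deterministic given the data; ties in the minimum break toward the
#' earlier column.
#'
#' @param data A `comparison_dataset`.
#' @param features Feature names to score.
#' @return A list of class `feature_importance`: `scores` (named numeric in
#'   the input feature order) and `ranking` (names sorted by decreasing
#'   importance, stable in input order on ties).
#' @export
rank_importance <- function(data, features) {
  sub <- subset_features(data, features)
  x <- sub$features
  sds <- apply(x, 2, stats::sd)
  live <- sds > 0
  scores <- stats::setNames(numeric(length(features)), features)
  if (any(live)) {
    xs <- standardize_apply(x[, live, drop = FALSE],
                            standardize_fit(x[, live, drop = FALSE]))
    fit <- logistic_fit(xs, sub$label)
    sc <- abs(fit$coef[-1])
    sc[is.na(sc)] <- 0   # aliased (collinear) columns carry no information
    scores[features[live]] <- sc
  }
  ord <- order(-scores)  # stable: ties keep input order
  structure(list(scores = scores, ranking = features[ord]),
            class = "feature_importance")
}

evaluate_set <- function(data, features, configs, cv_folds, seed) {
  aic <- compute_aic(data, features)
  cv <- cross_validate(subset_features(data, features), configs,
                       k = cv_folds, seed = seed)
  list(aic = aic, accuracy = cv$report$accuracy)
}

#' Recursive feature elimination with a joint AIC/accuracy stopping rule
#'
#' Starting from the full feature set, each iteration scores the current set
#' by its logistic AIC and its cross-validated hard-voting-ensemble accuracy,
#' then eliminates the least-important feature (smallest absolute
#' standardized logistic coefficient). Elimination stops when the candidate
#' set after removal is worse than the incumbent on *both* criteria (higher
#' AIC and lower accuracy), or when a single feature remains — no predefined
#' target size is needed. The accepted set is the visited set with minimal
#' AIC among those attaining the best accuracy seen (AIC prefers smaller
#' models; accuracy guarantees the highest-performing one).
#'
#' @param data A `comparison_dataset` with at least two features.
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed driving fold assignment and member fits.
#' @param configs Member configurations, see [default_member_configs()].
#' @return A list of class `feature_selection_trace` with `iterations`
#'   (data.frame: size, features, eliminated, aic, log_likelihood,
#'   cv_accuracy), `accepted_set`, `stop_reason`.
#' @export
select_rfe_aic <- function(data, cv_folds = 10, seed,
                           configs = default_member_configs()) {
  if (missing(seed)) stop("selection seed must be given explicitly")
  feats <- data$feature_names
  if (length(feats) < 1) stop("at least one feature required")
  if (any(data$class_counts < cv_folds)) {
    stop("each class needs at least cv_folds rows")
  }

  iters <- list()
  record <- function(features, eliminated, ev) {
    iters[[length(iters) + 1L]] <<- list(
      size = length(features), features = list(features),
      eliminated = eliminated, aic = ev$aic$aic,
      log_likelihood = ev$aic$log_likelihood, cv_accuracy = ev$accuracy)
  }

  current <- feats
  ev <- evaluate_set(data, current, configs, cv_folds,
                     derive_seed(seed, "cv", length(current)))
  stop_reason <- NULL
  repeat {
    if (length(current) == 1L) {
      record(current, NA_character_, ev)
      stop_reason <- stop_reason %||% "singleton"
      break
    }
    imp <- rank_importance(data, current)
    f_min <- current[which.min(imp$scores)]
    record(current, f_min, ev)
    candidate <- setdiff(current, f_min)
    ev_cand <- evaluate_set(data, candidate, configs, cv_folds,
                            derive_seed(seed, "cv", length(candidate)))
    if (ev_cand$aic$aic > ev$aic$aic &&
        ev_cand$accuracy < ev$accuracy) {
      record(candidate, NA_character_, ev_cand)
      stop_reason <- "candidate worse on both AIC and accuracy"
      break
    }
    current <- candidate
    ev <- ev_cand
  }

  trace <- do.call(rbind, lapply(iters, function(it) {
    data.frame(size = it$size, eliminated = it$eliminated, aic = it$aic,
               log_likelihood = it$log_likelihood,
               cv_accuracy = it$cv_accuracy, stringsAsFactors = FALSE)
  }))
  trace$features <- lapply(iters, function(it) it$features[[1]])

  best_acc <- max(trace$cv_accuracy)
  cand <- which(trace$cv_accuracy == best_acc)
  cand <- cand[order(trace$aic[cand], trace$size[cand])]
  accepted <- trace$features[[cand[1]]]

  structure(list(iterations = trace, accepted_set = accepted,
                 stop_reason = stop_reason),
            class = "feature_selection_trace")
}

#' @export
print.feature_selection_trace <- function(x, ...) {
  cat(sprintf("<feature_selection_trace> %d iterations, stop: %s\n",
              nrow(x$iterations), x$stop_reason))
  cat("accepted:", paste(x$accepted_set, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive AIC-minimising subset refinement ("custom model")
#'
#' Enumerates every non-empty subset of the candidate set (typically the set
#' selected on the synthetic dataset), computes each subset's logistic AIC on
#' the given data (typically the original dataset), and returns the
#' AIC-minimal subset. Ties break toward the smaller subset, then toward the
#' lexicographically earlier one in the candidate feature order. Candidate
#' sets larger than 12 features are refused unless `greedy = TRUE`, in which
#' case backward elimination on AIC is used instead of full enumeration.
#'
#' @param data A `comparison_dataset` (the data whose AIC is minimised).
#' @param candidate_set Character vector of feature names, a subset of
#'   `data$feature_names`.
#' @param greedy Use greedy backward elimination for large candidate sets.
#' @return Character vector: the selected feature subset.
#' @export
refine_custom_subset <- function(data, candidate_set, greedy = FALSE) {
  stopifnot(length(candidate_set) >= 1,
            all(candidate_set %in% data$feature_names))
  p <- length(candidate_set)
  if (p > 12 && !greedy) {
    stop("candidate set larger than 12 features; use greedy = TRUE")
  }
  if (p > 12) {
    current <- candidate_set
    best <- compute_aic(data, current)$aic
    repeat {
      if (length(current) == 1L) return(current)
      aics <- vapply(current, function(f) {
        compute_aic(data, setdiff(current, f))$aic
      }, numeric(1))
      if (min(aics) >= best) return(current)
      current <- setdiff(current, current[which.min(aics)])
      best <- min(aics)
    }
  }
  # enumerate by increasing size, lexicographic within size, keep first best
  best_aic <- Inf
  best_set <- NULL
  for (size in seq_len(p)) {
    sets <- utils::combn(candidate_set, size, simplify = FALSE)
    for (s in sets) {
      a <- compute_aic(data, s)$aic
      if (a < best_aic - 1e-12) {
        best_aic <- a
        best_set <- s
      }
    }
  }
  best_set
}
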