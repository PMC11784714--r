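# The five-member hard-voting ensemble: L2-regularized logistic regression,
# a single-hidden-layer perceptron, an RBF support vector machine, K-nearest
# neighbours and a nearest-centroid classifier, combined by unweighted
# majority vote, with stratified k-fold cross-validation.

member_types <- function() c("LR", "ANN", "SVM", "KNN", "NEARCENT")

#' Configuration for one ensemble member
#'
#' @param member One of `"LR"`, `"ANN"`, `"SVM"`, `"KNN"`, `"NEARCENT"`.
#' @param ... Hyperparameters overriding the member's defaults:
#'   LR `lambda` (L2 penalty on standardized features, default 1 = C of 1);
#'   ANN `size` (hidden units, 16), `maxit` (2000), `decay` (0);
#'   SVM `cost` (1), RBF kernel with gamma `1/p`;
#'   KNN `k` (5, must be odd), Euclidean distance;
#'   NEARCENT none (Euclidean centroids).
#' @return A list of class `member_config`.
#' @export
member_config <- function(member, ...) {
  member <- match.arg(member, member_types())
  defaults <- switch(member,
    LR = list(lambda = 1),
    ANN = list(size = 16, maxit = 2000, decay = 0),
    SVM = list(cost = 1),
    KNN = list(k = 5),
    NEARCENT = list())
  hp <- utils::modifyList(defaults, list(...))
  if (member == "KNN" && hp$k %% 2 == 0) stop("KNN neighbour count must be odd")
  structure(list(member = member, hyperparameters = hp),
            class = "member_config")
}

#' Default configurations for the five ensemble members
#' @return A named list of five [member_config()] objects.
#' @export
default_member_configs <- function() {
  stats::setNames(lapply(member_types(), member_config), member_types())
}

fit_member <- function(cfg, xs, y, seed) {
  hp <- cfg$hyperparameters
  fit <- switch(cfg$member,
    LR = ridge_logistic(xs, y, lambda = hp$lambda),
    ANN = with_seed(seed, {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), xs,
                       check.names = FALSE)
      nnet::nnet(.y ~ ., data = df, size = hp$size, maxit = hp$maxit,
                 decay = hp$decay, trace = FALSE)
    }),
    SVM = e1071::svm(xs, factor(y, levels = c(0, 1)), kernel = "radial",
                     cost = hp$cost, scale = FALSE),
    KNN = list(x = xs, y = y, k = min(hp$k, nrow(xs))),
    NEARCENT = list(centroids = rbind(
      `0` = colMeans(xs[y == 0, , drop = FALSE]),
      `1` = colMeans(xs[y == 1, , drop = FALSE]))))
  list(config = cfg, fit = fit)
}

predict_member <- function(member, xs) {
  fit <- member$fit
  switch(member$config$member,
    LR = as.integer(drop(cbind(1, xs) %*% member$fit$coef) >= 0),
    ANN = as.integer(as.character(
      stats::predict(fit, data.frame(xs, check.names = FALSE),
                     type = "class"))),
    SVM = as.integer(as.character(stats::predict(fit, xs))),
    KNN = as.integer(as.character(
      class::knn(fit$x, xs, factor(fit$y, levels = c(0, 1)), k = fit$k))),
    NEARCENT = {
      d0 <- rowSums(sweep(xs, 2, fit$centroids["0", ], "-")^2)
      d1 <- rowSums(sweep(xs, 2, fit$centroids["1", ], "-")^2)
      as.integer(d1 < d0)  # tie goes to class 0
    })
}

#' Fit the five-member hard-voting ensemble
#'
#' Features are standardized on the training rows (the learned centring and
#' scaling travel with the model, so validation rows never leak into it);
#' each member is then fitted on the standardized training matrix.
#' Deterministic given the seed.
#'
#' @param train A `comparison_dataset`.
#' @param configs Named list of five [member_config()]s.
#' @param seed Integer seed (drives the perceptron's weight initialisation).
#' @return A list of class `ensemble_model`.
#' @export
fit_ensemble <- function(train, configs = default_member_configs(),
                         seed = 1) {
  if (length(configs) != 5L ||
      !setequal(vapply(configs, `[[`, "", "member"), member_types())) {
    stop("exactly the five declared members are required")
  }
  if (length(unique(train$label)) < 2L) {
    stop("single-class training data: cannot fit ensemble")
  }
  std <- standardize_fit(train$features)
  xs <- standardize_apply(train$features, std)
  members <- lapply(configs, function(cfg) {
    fit_member(cfg, xs, train$label, derive_seed(seed, cfg$member))
  })
  structure(list(members = members, feature_names = train$feature_names,
                 standardization = std),
            class = "ensemble_model")
}

#' Predict classes by majority vote of the five members
#'
#' With five voters and two classes a tie is impossible.
#'
#' @param model An `ensemble_model`.
#' @param rows Numeric matrix with the model's feature columns.
#' @return Integer vector of 0/1 class votes, one per row.
#' @export
predict_vote <- function(model, rows) {
  rows <- as.matrix(rows)
  if (is.null(colnames(rows))) colnames(rows) <- model$feature_names
  if (!identical(colnames(rows), model$feature_names)) {
    stop("feature mismatch: expected ",
         paste(model$feature_names, collapse = ", "))
  }
  xs <- standardize_apply(rows, model$standardization)
  votes <- vapply(model$members, predict_member, integer(nrow(xs)), xs = xs)
  if (nrow(xs) == 1L) votes <- matrix(votes, nrow = 1)
  as.integer(rowSums(votes) >= 3)
}

#' Assign rows to cross-validation folds
#'
#' Stratified assignment shuffles rows within each class and deals them into
#' folds with a single running counter, so fold sizes differ by at most one
#' both overall and within every class.
#'
#' @param n Number of rows.
#' @param labels Per-row class labels (used when `stratified`).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify folds by class (default). With stratification
#'   every class must have at least `k` rows; there is no silent fallback.
#' @return A list of class `fold_assignment`: `fold_of_row` (1..k), `k`,
#'   `seed`, `stratified`.
#' @export
make_folds <- function(n, labels, k, seed, stratified = TRUE) {
  if (n < k) stop("fewer rows than folds")
  if (stratified) {
    counts <- table(labels)
    small <- counts < k
    if (any(small)) {
      stop("stratification error: class ", names(counts)[small][1],
           " has fewer than ", k, " rows")
    }
  }
  with_seed(seed, {
    ord <- if (stratified) {
      unlist(lapply(sort(unique(labels)), function(cl) {
        idx <- which(labels == cl)
        idx[sample.int(length(idx))]
      }), use.names = FALSE)
    } else {
      sample.int(n)
    }
    fold <- integer(n)
    fold[ord] <- rep_len(seq_len(k), n)
    structure(list(fold_of_row = fold, k = k, seed = seed,
                   stratified = stratified),
              class = "fold_assignment")
  })
}

#' Cross-validate the hard-voting ensemble
#'
#' For each fold, fits the ensemble on the remaining folds and votes on the
#' held-out rows, so every row receives exactly one out-of-fold prediction.
#' Metrics are computed on the pooled out-of-fold confusion counts (primary)
#' and, secondarily, as per-fold means.
#'
#' @param data A `comparison_dataset`.
#' @param configs Five [member_config()]s.
#' @param k Number of folds.
#' @param seed Integer seed (folds and member fits).
#' @param stratified Stratify folds by class.
#' @param folds Optional precomputed `fold_assignment` (overrides
#'   `k`/`seed`/`stratified` for the assignment).
#' @return A list of class `cv_result`: `predictions` (per-row out-of-fold
#'   votes), `report` (pooled `metric_report`), `fold_mean` (named means of
#'   the five metrics across folds, NA-removed), `folds`.
#' @export
cross_validate <- function(data, configs = default_member_configs(), k = 10,
                           seed, stratified = TRUE, folds = NULL) {
  if (missing(seed) && is.null(folds)) stop("cross-validation seed required")
  if (is.null(folds)) {
    folds <- make_folds(nrow(data$features), data$label, k,
                        derive_seed(seed, "folds"), stratified)
  }
  k <- folds$k
  pred <- rep(NA_integer_, nrow(data$features))
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- folds$fold_of_row == f
    train <- comparison_dataset(data$features[!hold, , drop = FALSE],
                                data$label[!hold], data$spec, data$source)
    model <- fit_ensemble(train, configs, seed = derive_seed(folds$seed,
                                                             "fit", f))
    pred[hold] <- predict_vote(model, data$features[hold, , drop = FALSE])
    fm <- compute_metrics(confusion(data$label[hold], pred[hold]))
    fold_metrics[[f]] <- unlist(fm[c("sensitivity", "specificity",
                                     "precision", "accuracy", "f1")])
  }
  report <- compute_metrics(confusion(data$label, pred),
                            aggregation = "pooled")
  fold_mat <- do.call(rbind, fold_metrics)
  structure(list(predictions = pred, report = report,
                 fold_mean = colMeans(fold_mat, na.rm = TRUE),
                 folds = folds),
            class = "cv_result")
}
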