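test_that("AIC satisfies its identity and matches a direct log-likelihood sum", {
  d <- blob_dataset(n_per_class = 10, gap = 1, p_signal = 1, p_noise = 1,
                    seed = 21)
  res <- compute_aic(d, c("signal1", "noise1"))
  expect_s3_class(res, "aic_result")
  expect_equal(res$k, 3L)
  expect_identical(res$aic, 2 * res$k - 2 * res$log_likelihood)

  # oracle: refit with glm, then sum the Bernoulli log-density by hand
  df <- data.frame(y = d$label, d$features)
  fit <- glm(y ~ signal1 + noise1, df, family = binomial())
  p <- fitted(fit)
  ll_oracle <- sum(d$label * log(p) + (1 - d$label) * log(1 - p))
  expect_equal(res$log_likelihood, ll_oracle, tolerance = 1e-8)
  expect_false(res$separated)
})

test_that("perfect separation yields a finite, flagged AIC", {
  d <- blob_dataset(n_per_class = 25, gap = 8, seed = 22)
  res <- compute_aic(d, "signal1")
  expect_true(res$separated)
  expect_true(is.finite(res$aic))
  # likelihood approaches 1 under separation, so AIC approaches 2k
  expect_equal(res$aic, 2 * res$k, tolerance = 1e-3)
})

test_that("importance ranks an informative feature above pure noise", {
  d <- blob_dataset(n_per_class = 30, gap = 6, p_signal = 1, p_noise = 1,
                    seed = 23)
  imp <- rank_importance(d, c("noise1", "signal1"))
  expect_equal(imp$ranking[1], "signal1")
  expect_equal(sort(names(imp$scores)), sort(c("noise1", "signal1")))

  expect_equal(rank_importance(d, "signal1")$ranking, "signal1")

  # zero-variance feature scores 0
  x <- cbind(d$features, flat = 0)
  d2 <- comparison_dataset(x, d$label, d$spec, "original")
  expect_equal(unname(rank_importance(d2, colnames(x))$scores["flat"]), 0)

  # an exact duplicate column is aliased in the ML fit and scores 0
  d4 <- blob_dataset(n_per_class = 30, gap = 1, p_signal = 1, seed = 24)
  x3 <- cbind(d4$features[, "signal1", drop = FALSE],
              signal1b = d4$features[, "signal1"])
  d3 <- comparison_dataset(x3, d4$label, d4$spec, "original")
  sc <- rank_importance(d3, colnames(x3))$scores
  expect_equal(unname(sc["signal1b"]), 0)
})

test_that("adding pure noise does not lower AIC on average", {
  deltas <- vapply(1:30, function(s) {
    d <- blob_dataset(n_per_class = 25, gap = 1.5, p_signal = 1,
                      p_noise = 1, seed = 100 + s)
    compute_aic(d, c("signal1", "noise1"))$aic -
      compute_aic(d, "signal1")$aic
  }, numeric(1))
  expect_gt(mean(deltas), -0.2)
})

test_that("RFE traces shrink monotonically and accept a visited set", {
  for (s in 1:3) {
    d <- blob_dataset(n_per_class = 40, gap = 3, p_signal = 2, p_noise = 3,
                      seed = 300 + s)
    tr <- select_rfe_aic(d, cv_folds = 10, seed = 400 + s)
    it <- tr$iterations
    expect_equal(it$size, seq(max(it$size), by = -1,
                              length.out = nrow(it)))
    # eliminated features never reappear
    elim <- it$eliminated[!is.na(it$eliminated)]
    for (i in seq_along(elim)) {
      later <- unlist(it$features[-seq_len(i)])
      expect_false(elim[i] %in% later)
    }
    # accepted set is one of the visited sets, at the best accuracy seen
    expect_true(any(vapply(it$features, setequal, logical(1),
                           tr$accepted_set)))
    acc_idx <- which(vapply(it$features, setequal, logical(1),
                            tr$accepted_set))
    expect_equal(it$cv_accuracy[acc_idx[1]], max(it$cv_accuracy))
    # determinism under the same seed
    tr2 <- select_rfe_aic(d, cv_folds = 10, seed = 400 + s)
    expect_identical(tr$iterations$aic, tr2$iterations$aic)
    expect_identical(tr$accepted_set, tr2$accepted_set)
  }
})

test_that("single-feature input stops immediately", {
  d <- blob_dataset(n_per_class = 15, gap = 2, seed = 31)
  tr <- select_rfe_aic(d, cv_folds = 10, seed = 1)
  expect_equal(tr$accepted_set, "signal1")
  expect_equal(nrow(tr$iterations), 1)
  expect_equal(tr$stop_reason, "singleton")
  expect_true(all(is.na(tr$iterations$eliminated)))
})

test_that("custom refinement equals exhaustive enumeration", {
  d <- blob_dataset(n_per_class = 25, gap = 1.5, p_signal = 2, p_noise = 1,
                    seed = 33)
  feats <- d$feature_names
  # independent brute-force oracle over all 7 subsets via glm's own AIC
  subsets <- unlist(lapply(1:3, combn, x = feats, simplify = FALSE),
                    recursive = FALSE)
  aics <- vapply(subsets, function(s) {
    df <- data.frame(y = d$label, d$features[, s, drop = FALSE])
    glm(y ~ ., df, family = binomial())$aic
  }, numeric(1))
  oracle <- subsets[[which.min(aics)]]
  picked <- refine_custom_subset(d, feats)
  expect_setequal(picked, oracle)
  expect_true(all(picked %in% feats))
  expect_lte(compute_aic(d, picked)$aic, compute_aic(d, feats)$aic)

  expect_equal(refine_custom_subset(d, "signal1"), "signal1")
  expect_error(refine_custom_subset(d, rep(feats, 5)[1:13]),
               "greedy")
})
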