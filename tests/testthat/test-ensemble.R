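test_that("member configuration validates its inputs", {
  expect_error(member_config("KNN", k = 4), "odd")
  expect_equal(member_config("ANN")$hyperparameters$size, 16)
  cfgs <- default_member_configs()
  expect_setequal(names(cfgs), c("LR", "ANN", "SVM", "KNN", "NEARCENT"))
})

test_that("nearest-centroid stores the class means of the training rows", {
  x <- matrix(c(0, 4, 1, 5), 2, dimnames = list(NULL, c("a", "b")))
  d <- comparison_dataset(x, c(0L, 1L), comparison_spec(1, "CN", "AD"),
                          "original")
  model <- fit_ensemble(d, seed = 1)
  xs <- cogstage:::standardize_apply(x, model$standardization)
  cent <- model$members$NEARCENT$fit$centroids
  expect_equal(unname(cent["0", ]), unname(xs[1, ]))
  expect_equal(unname(cent["1", ]), unname(xs[2, ]))
})

test_that("every member separates two well-separated blobs on training data", {
  d <- blob_dataset(n_per_class = 50, gap = 6, p_signal = 2, seed = 41)
  model <- fit_ensemble(d, seed = 2)
  xs <- cogstage:::standardize_apply(d$features, model$standardization)
  for (m in names(model$members)) {
    pred <- cogstage:::predict_member(model$members[[m]], xs)
    expect_equal(pred, d$label, info = m)
  }
  # single-class training data is rejected at construction
  expect_error(comparison_dataset(d$features[1:5, ], rep(0L, 5), d$spec,
                                  "original"),
               "both classes")
})

test_that("ensemble fits are deterministic given the seed", {
  d <- blob_dataset(n_per_class = 30, gap = 1, p_signal = 3, seed = 43)
  probe <- matrix(rnorm(60), 20, 3,
                  dimnames = list(NULL, d$feature_names))
  m1 <- fit_ensemble(d, seed = 7)
  m2 <- fit_ensemble(d, seed = 7)
  expect_identical(predict_vote(m1, probe), predict_vote(m2, probe))
})

test_that("the hard vote equals the independently computed mode of the members", {
  d <- blob_dataset(n_per_class = 40, gap = 0.8, p_signal = 2, p_noise = 2,
                    seed = 44)
  model <- fit_ensemble(d, seed = 3)
  probe <- matrix(rnorm(200), 50, 4,
                  dimnames = list(NULL, d$feature_names))
  vote <- predict_vote(model, probe)
  xs <- cogstage:::standardize_apply(probe, model$standardization)
  indiv <- sapply(model$members, cogstage:::predict_member, xs = xs)
  oracle <- apply(indiv, 1, function(v) {
    tab <- table(v)
    as.integer(names(tab)[which.max(tab)])
  })
  expect_equal(vote, unname(oracle))
  # five binary voters cannot tie
  expect_true(all(rowSums(indiv) != 2.5))
  expect_error(predict_vote(model, matrix(0, 1, 2,
                                          dimnames = list(NULL, c("x", "y")))),
               "feature mismatch")
})

test_that("fold assignment is balanced overall and within classes", {
  labels <- rep(0:1, each = 10)
  fa <- make_folds(20, labels, 10, seed = 5)
  expect_equal(sort(unique(fa$fold_of_row)), 1:10)
  expect_true(all(table(fa$fold_of_row) == 2))
  # stratification: one row of each class per fold
  expect_true(all(table(fa$fold_of_row, labels) == 1))

  labels23 <- c(rep(0, 12), rep(1, 11))
  fa23 <- make_folds(23, labels23, 10, seed = 6)
  sizes <- table(fa23$fold_of_row)
  expect_equal(sum(sizes), 23)
  expect_true(all(sizes %in% 2:3))
  for (cl in 0:1) {
    per <- table(factor(fa23$fold_of_row[labels23 == cl], levels = 1:10))
    expect_lte(max(per) - min(per), 1)
  }

  expect_error(make_folds(9, rep(0:1, length.out = 9), 10, seed = 1),
               "fewer rows than folds")
  expect_error(make_folds(20, c(rep(0, 15), rep(1, 5)), 10, seed = 1),
               "stratification error")
})

test_that("cross-validation scores every row once and nails separable data", {
  d <- blob_dataset(n_per_class = 30, gap = 8, seed = 45)
  # verified separation: every member should classify held-out rows correctly
  expect_gt(min(d$features[d$label == 1, 1]),
            max(d$features[d$label == 0, 1]))
  cv <- cross_validate(d, k = 10, seed = 9)
  expect_false(anyNA(cv$predictions))
  expect_length(cv$predictions, 60)
  counts <- cv$report$counts
  expect_equal(counts$TP + counts$TN + counts$FP + counts$FN, 60)
  expect_equal(cv$report$accuracy, 1.0)
})

test_that("leave-one-out cross-validation matches an independent loop", {
  d <- blob_dataset(n_per_class = 6, gap = 1.2, p_signal = 2, seed = 46)
  n <- 12
  cv <- cross_validate(d, k = n, seed = 17, stratified = FALSE)
  fa <- make_folds(n, d$label, n, derive_seed(17, "folds"),
                   stratified = FALSE)
  oracle <- rep(NA_integer_, n)
  for (f in seq_len(n)) {
    hold <- fa$fold_of_row == f
    train <- comparison_dataset(d$features[!hold, , drop = FALSE],
                                d$label[!hold], d$spec, d$source)
    model <- fit_ensemble(train, seed = derive_seed(fa$seed, "fit", f))
    oracle[hold] <- predict_vote(model, d$features[hold, , drop = FALSE])
  }
  expect_equal(cv$predictions, oracle)
})

test_that("standardization is learned from training rows only", {
  d <- blob_dataset(n_per_class = 20, gap = 1, p_signal = 2, seed = 47)
  model <- fit_ensemble(d, seed = 1)
  expect_equal(model$standardization$center, colMeans(d$features))
  expect_equal(model$standardization$scale, apply(d$features, 2, sd))
})
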