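test_that("confusion counts match hand tallies and a brute-force loop", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(cc[c("TP", "FN", "TN", "FP")]),
               c(TP = 1L, FN = 1L, TN = 1L, FP = 1L))

  ident <- confusion(c(0, 1, 1), c(0, 1, 1))
  expect_equal(ident$FP + ident$FN, 0L)

  set.seed(60)
  truth <- rbinom(1000, 1, 0.4)
  pred <- rbinom(1000, 1, 0.5)
  cc2 <- confusion(truth, pred)
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(1000)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1L
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1L
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1L
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1L
  }
  expect_equal(unlist(cc2[c("TP", "TN", "FP", "FN")]),
               c(TP = tp, TN = tn, FP = fp, FN = fn))
  expect_equal(cc2$TP + cc2$TN + cc2$FP + cc2$FN, 1000L)
  expect_error(confusion(c(0, 1), c(1)), "length mismatch")
  expect_error(confusion(c(0, 2), c(1, 1)), "0/1")
})

test_that("metrics follow their formulas with declared undefined semantics", {
  m <- compute_metrics(confusion(c(1, 1, 1, 1), c(1, 1, 1, 0)))
  expect_equal(m$sensitivity, 0.75)

  # no positive rows scored: sensitivity undefined, precision a defined zero
  cc <- structure(list(TP = 0L, TN = 5L, FP = 3L, FN = 0L),
                  class = "confusion_counts")
  m2 <- compute_metrics(cc)
  expect_true(is.na(m2$sensitivity))
  expect_equal(m2$precision, 0)
  expect_true(is.na(m2$f1))
  expect_equal(m2$specificity, 5 / 8)

  # harmonic-mean fixed point
  cc3 <- structure(list(TP = 1L, TN = 0L, FP = 1L, FN = 1L),
                   class = "confusion_counts")
  m3 <- compute_metrics(cc3)
  expect_equal(m3$precision, 0.5)
  expect_equal(m3$sensitivity, 0.5)
  expect_equal(m3$f1, 0.5)
})

test_that("metric identities and range hold over random counts", {
  set.seed(61)
  for (i in 1:200) {
    cc <- structure(as.list(stats::setNames(rpois(4, 5),
                                            c("TP", "TN", "FP", "FN"))),
                    class = "confusion_counts")
    m <- compute_metrics(cc)
    n <- cc$TP + cc$TN + cc$FP + cc$FN
    if (n > 0) expect_equal(m$accuracy, (cc$TP + cc$TN) / n)
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN))
    }
    for (v in unlist(m[c("sensitivity", "specificity", "precision",
                         "accuracy", "f1")])) {
      if (!is.na(v)) expect_true(v >= 0 && v <= 1)
    }
    # polarity swap: sensitivity <-> specificity, precision -> NPV
    swapped <- structure(list(TP = cc$TN, TN = cc$TP, FP = cc$FN,
                              FN = cc$FP),
                         class = "confusion_counts")
    ms <- compute_metrics(swapped)
    expect_equal(ms$sensitivity, m$specificity)
    expect_equal(ms$specificity, m$sensitivity)
    npv <- if (cc$TN + cc$FN == 0) NA_real_ else cc$TN / (cc$TN + cc$FN)
    expect_equal(ms$precision, npv)
  }
})

test_that("group summaries report sample means and SDs", {
  x <- matrix(c(1, 3, 5, 5, 5, 2), 3,
              dimnames = list(NULL, c("a", "b")))
  ct <- cohort_table(x, diagnosis = c(0L, 0L, 4L))
  gs <- summarize_groups(ct)
  cn_a <- gs[gs$group == "CN" & gs$feature == "a", ]
  expect_equal(cn_a$mean, 2)
  expect_equal(cn_a$sd, sqrt(2))
  expect_equal(gs[gs$group == "CN" & gs$feature == "b", "sd"], 0)
  expect_true(is.na(gs[gs$group == "AD" & gs$feature == "a", "sd"]))

  # two-pass oracle on a larger fixture
  enc <- study_cohort(seed = 9)
  gs2 <- summarize_groups(enc$cohort)
  grp <- decode_diagnosis(enc$cohort$diagnosis)
  for (g in unique(grp)) {
    rows <- enc$cohort$features[grp == g, "ADAS13"]
    mu <- sum(rows) / length(rows)
    s2 <- sum((rows - mu)^2) / (length(rows) - 1)
    row <- gs2[gs2$group == g & gs2$feature == "ADAS13", ]
    expect_equal(row$mean, mu)
    expect_equal(row$sd, sqrt(s2))
  }
})

test_that("reports render in the published layout", {
  mk <- function(tp, tn, fp, fn) {
    compute_metrics(structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
                              class = "confusion_counts"))
  }
  perfect <- mk(10, 10, 0, 0)
  undef <- mk(0, 5, 3, 0)
  res <- list(CN_vs_AD = list(original = perfect, synthetic = perfect,
                              custom = perfect),
              LMCI_vs_AD = list(original = undef, synthetic = perfect,
                                custom = perfect))
  tab <- render_report(res)
  expect_equal(tab$CN_vs_AD.Orig[tab$Metric == "Sensitivity"], "1.0000")
  expect_equal(tab$LMCI_vs_AD.Orig[tab$Metric == "Sensitivity"], "NA")
  expect_equal(tab$LMCI_vs_AD.Orig[tab$Metric == "Precision"], "0.0000")

  res$CN_vs_AD$synthetic <- NULL
  expect_error(render_report(res), "missing metric cell")

  path <- withr::local_tempfile(fileext = ".md")
  render_report(res["LMCI_vs_AD"], path)
  expect_true(any(grepl("\\| NA \\|", readLines(path))))
})
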