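# Fixtures built in code; no data files.

# A 10-row ADNIMERGE-dialect frame where exactly rows 1-4 jointly satisfy
# the inclusion criteria (hand-checked): row 5 misses VISCODE, row 6 is too
# young, row 7 too old, row 8 non-Hispanic, row 9 has unknown ethnicity,
# row 10 fails on age *and* ethnicity (counted once, at the age step).
tiny_adnimerge <- function() {
  n <- 10
  df <- data.frame(
    VISCODE = c("bl", "m06", "bl", "bl", NA, "bl", "bl", "bl", "bl", "bl"),
    SITE = 101:110,
    AGE = c(53, 70.2, 95, 80, 75, 52.9, 95.1, 60, 61, 40),
    PTGENDER = rep(c("Female", "Male"), 5),
    PTEDUCAT = rep(16, n),
    PTETHCAT = c(rep("Hisp/Latino", 7), "Not Hisp/Latino", "Unknown",
                 "Not Hisp/Latino"),
    PTRACCAT = rep("White", n),
    PTMARRY = rep(c("Married", "Widowed"), 5),
    DX.bl = c("CN", "SMC", "EMCI", "LMCI", "AD", "CN", "SMC", "EMCI",
              "LMCI", "AD"),
    stringsAsFactors = FALSE, check.names = FALSE)
  for (f in setdiff(table4_features(),
                    c("AGE", "PTGENDER", "PTMARRY"))) {
    df[[f]] <- seq(1, 2, length.out = n)
  }
  as_raw_cohort(df)
}

# Two Gaussian blobs separated by `gap` pooled SDs on `p_signal` features,
# plus `p_noise` pure-noise features.
blob_dataset <- function(n_per_class = 50, gap = 4, p_signal = 1,
                         p_noise = 0, seed = 1,
                         spec = comparison_spec(1, "CN", "AD")) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(0:1, each = n_per_class)
  x <- matrix(rnorm(n * (p_signal + p_noise)), n)
  for (j in seq_len(p_signal)) x[y == 1, j] <- x[y == 1, j] + gap
  colnames(x) <- c(paste0("signal", seq_len(p_signal)),
                   if (p_noise > 0) paste0("noise", seq_len(p_noise)))
  comparison_dataset(x, y, spec, "original")
}

# The study-condition cohort: generated raw frame -> filtered, encoded table.
study_cohort <- function(seed = 42) {
  raw <- generate_fixture(fixture_spec(seed = seed))
  fl <- apply_inclusion_criteria(raw)
  encode_and_complete(fl$cohort, fl$report)
}

# Small clean fixture spec: five groups, no missingness, no contamination.
clean_spec <- function(n = 30, seed = 7) {
  fixture_spec(
    n_per_group = stats::setNames(rep(n, 5),
                                  c("CN", "SMC", "EMCI", "LMCI", "AD")),
    missing_rate = 0, seed = seed,
    n_missing_viscode = 0, n_age_out = 0, n_non_hispanic = 0)
}
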