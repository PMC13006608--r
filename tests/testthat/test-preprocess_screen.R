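# independent recomputation of the audit's change score, written from its
# published definition rather than the package internals
oracle_change_score <- function(imputed, original) {
  affected <- names(original)[vapply(original, anyNA, logical(1))]
  if (!length(affected)) return(0)
  mean(vapply(affected, function(nm) {
    cc <- original[[nm]][!is.na(original[[nm]])]
    full <- imputed[[nm]]
    if (is.numeric(cc)) {
      abs(mean(full) - mean(cc)) / sd(cc) +
        abs(var(full) - var(cc)) / var(cc)
    } else {
      levs <- unique(c(as.character(cc), as.character(full)))
      p <- table(factor(as.character(cc), levs)) / length(cc)
      q <- table(factor(as.character(full), levs)) / length(full)
      sum(abs(p - q)) / 2
    }
  }, numeric(1)))
}

test_that("imputation candidates never alter non-missing cells", {
  co <- quick_cohort(seed = 4L, missing_rate = 0.03)
  feats <- co[setdiff(names(co), c("patient_id", "outcome",
                                   "primary_dx_text", "other_dx_text"))]
  audit <- impute_select(feats, seed = 2L)
  expect_false(anyNA(audit$imputed))
  for (nm in names(feats)) {
    obs <- !is.na(feats[[nm]])
    expect_identical(audit$imputed[[nm]][obs], feats[[nm]][obs],
                     info = nm)
  }
})

test_that("the chosen method is the argmin of the audited change score", {
  set.seed(9)
  df <- data.frame(a = rlnorm(60, 3, 0.6), b = rnorm(60, 10, 2),
                   g = factor(sample(c("x", "y", "z"), 60, TRUE)))
  df$a[sample(60, 2)] <- NA
  df$b[sample(60, 2)] <- NA
  df$g[sample(60, 2)] <- NA
  audit <- impute_select(df, seed = 3L)
  expect_equal(unname(audit$scores[audit$chosen]), min(audit$scores))
  # scores match the independent recomputation for the deterministic fills
  for (m in c("mode", "mean", "median")) {
    refit <- switch(m,
      mode = traumaprog:::impute_mode_(df),
      mean = traumaprog:::impute_mean_(df),
      median = traumaprog:::impute_median_(df))
    expect_equal(unname(audit$scores[m]), oracle_change_score(refit, df),
                 tolerance = 1e-12, info = m)
  }
})

test_that("a complete table scores zero everywhere and ties break to mode", {
  df <- data.frame(a = 1:10, b = rnorm(10))
  audit <- impute_select(df, seed = 1L)
  expect_true(all(audit$scores == 0))
  expect_equal(audit$chosen, "mode")
  expect_identical(audit$imputed, df)
})

test_that("deterministic fills coincide on a constant column", {
  df <- data.frame(k = c(7, 7, 7, NA, 7), x = c(1, 2, 3, 4, 5))
  a_mode <- traumaprog:::impute_mode_(df)
  a_mean <- traumaprog:::impute_mean_(df)
  a_median <- traumaprog:::impute_median_(df)
  expect_equal(a_mode$k, a_mean$k)
  expect_equal(a_mean$k, a_median$k)
  expect_error(impute_select(data.frame(z = c(NA_real_, NA_real_))),
               "entirely missing")
})

test_that("mean imputation wins on a symmetric-outlier fixture", {
  # complete cases are symmetric around 10 with heavy tails; the mean fill
  # preserves the mean exactly and shrinks the variance least relative to
  # mode (tail value) fills; verified against the independent oracle
  df <- data.frame(v = c(2, 10, 10, 18, 2, 18, 10, NA, NA))
  audit <- impute_select(df, seed = 5L)
  fills <- list(mode = traumaprog:::impute_mode_(df),
                mean = traumaprog:::impute_mean_(df),
                median = traumaprog:::impute_median_(df))
  oracle <- vapply(fills, oracle_change_score, numeric(1), original = df)
  expect_equal(unname(audit$scores[names(oracle)]), unname(oracle),
               tolerance = 1e-12)
  # mean and median coincide here (both 10): the tie goes to the earlier
  # candidate in the fixed order, and mode (=10 too) precedes both
  expect_equal(unname(audit$scores["mean"]), unname(audit$scores["median"]))
})

test_that("univariate screen picks the test by type and normality", {
  co <- quick_cohort(80L, 80L, 60L, seed = 6L, missing_rate = 0)
  feats <- co[c("albumin", "heart_rate", "sex", "headache", "ais_head_neck")]
  rep_ <- univariate_screen(feats, co$outcome)
  expect_setequal(rep_$test[rep_$feature %in% c("sex", "headache")],
                  "chi_square")
  expect_true(all(rep_$test[rep_$feature %in% c("albumin", "heart_rate")]
                  %in% c("anova", "kruskal_wallis")))
  expect_true(all(rep_$p_value >= 0 & rep_$p_value <= 1, na.rm = TRUE))

  # normal-by-construction groups take the ANOVA path
  set.seed(7)
  norm_df <- data.frame(z = rnorm(220))
  g <- factor(sample(c("cure", "improved", "poor"), 220, TRUE))
  expect_equal(univariate_screen(norm_df, g)$test, "anova")
})

test_that("groups with permuted identical values give a zero KW statistic", {
  x <- data.frame(v = rep(c(1, 2, 3, 4), 3))
  g <- factor(rep(c("a", "b", "c"), each = 4))
  rep_ <- univariate_screen(x, g)
  expect_equal(rep_$statistic, 0, tolerance = 1e-12)
  expect_false(rep_$significant)
})

test_that("zero-variance features are flagged, not tested", {
  df <- data.frame(flat = rep(1, 30), ok = rnorm(30))
  g <- factor(rep(c("a", "b", "c"), each = 10))
  rep_ <- univariate_screen(df, g)
  expect_true(rep_$flagged[rep_$feature == "flat"])
  expect_equal(rep_$test[rep_$feature == "flat"], "none")
  expect_true(is.na(rep_$p_value[rep_$feature == "flat"]))
})

test_that("chi-square path reproduces the hand-computed statistic", {
  # 2x3 table, statistic computed from sum((O-E)^2/E) by hand
  x <- factor(rep(c("no", "yes"), times = c(60, 40)))
  g <- factor(c(rep("a", 30), rep("b", 20), rep("c", 10),
                rep("a", 10), rep("b", 10), rep("c", 20)))
  tab <- table(x, g)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  by_hand <- sum((tab - E)^2 / E)
  rep_ <- univariate_screen(data.frame(v = x), g)
  expect_equal(rep_$statistic, by_hand, tolerance = 1e-12)
})

test_that("screen flags a large injected shift with high power", {
  set.seed(15)
  g <- factor(rep(c("cure", "improved", "poor"), c(108, 130, 54)))
  hits <- vapply(1:20, function(i) {
    v <- rlnorm(292, log(30), 0.5)
    v[g == "poor"] <- rlnorm(54, log(50), 0.5)   # ~0.7 SD shift on log scale
    univariate_screen(data.frame(v = v), g)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("type-I error is near nominal over null replicates", {
  set.seed(16)
  g <- factor(rep(c("cure", "improved", "poor"), c(108, 130, 54)))
  sig <- vapply(1:400, function(i) {
    univariate_screen(data.frame(v = rnorm(292)), g)$significant
  }, logical(1))
  # 99% binomial band around 0.05 for 400 replicates
  expect_gte(mean(sig), 0.022)
  expect_lte(mean(sig), 0.081)
})

test_that("timeliness filter removes named features, preserving order", {
  rep_ <- data.frame(feature = paste0("f", 1:25),
                     significant = c(rep(TRUE, 21), rep(FALSE, 4)))
  kept <- timeliness_filter(rep_, c("f3", "f17"))
  expect_equal(length(kept), 19L)
  expect_identical(kept, setdiff(paste0("f", 1:21), c("f3", "f17")))
  expect_identical(timeliness_filter(rep_, character(0)),
                   paste0("f", 1:21))
  # excluding a non-significant feature is a no-op
  expect_identical(timeliness_filter(rep_, "f24"),
                   timeliness_filter(rep_, character(0)))
})
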