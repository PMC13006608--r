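study_shaped_xy <- function(seed = 1L) {
  co <- generate_cohort(cohort_spec(seed = seed, missing_rate = 0))
  y <- dichotomize_outcome(co$outcome)
  x <- co[c("albumin", "ada", "heart_rate", "hb", "ast", "creatinine",
            "prealbumin", "cholinesterase")]
  list(x = as.matrix(x), y = y)
}

test_that("rebalance 'none' is the identity", {
  d <- study_shaped_xy(2L)
  rb <- rebalance(d$x, d$y, method = "none", seed = 1L)
  expect_identical(rb$x, d$x)
  expect_identical(rb$y, d$y)
  expect_equal(rb$ratio_before, rb$ratio_after)
})

test_that("SMOTE-ENN lifts the study-shaped minority above the 1:4 bound", {
  for (seed in 1:10) {
    d <- study_shaped_xy(seed)
    rb <- rebalance(d$x, d$y, method = "smote_enn", seed = seed)
    expect_lt(rb$ratio_after, 4)
    expect_true(all(rb$counts_after > 0))
    expect_equal(rb$ratio_before, 238 / 54, tolerance = 1e-12)
  }
})

test_that("every synthetic SMOTE point is a convex combination of two minority originals", {
  d <- study_shaped_xy(3L)
  sm <- smote(d$x, d$y, k = 5L, seed = 9L)
  minority <- levels(d$y)[which.min(table(d$y))]
  expect_true(all(sm$y[sm$synthetic] == minority))
  pars <- sm$parents
  synth_rows <- which(sm$synthetic)
  for (i in seq_along(synth_rows)) {
    expected <- d$x[pars[i, "a"], ] * (1 - pars[i, "lambda"]) +
      d$x[pars[i, "b"], ] * pars[i, "lambda"]
    expect_equal(unname(sm$x[synth_rows[i], ]), unname(expected),
                 tolerance = 1e-12)
    expect_true(all(d$y[pars[i, c("a", "b")]] == minority))
  }
  expect_error(smote(d$x[1:10, ], factor(c(rep("good", 7), rep("poor", 3)),
                                         c("good", "poor")), k = 5L),
               "exceed")
})

test_that("ENN deletes rows but never edits surviving ones", {
  d <- study_shaped_xy(4L)
  sm <- smote(d$x, d$y, seed = 5L)
  cleaned <- enn(sm$x, sm$y, k = 3L)
  expect_true(nrow(cleaned$x) <= nrow(sm$x))
  expect_identical(cleaned$x, sm$x[cleaned$kept, , drop = FALSE])
  # original majority rows that survive are untouched
  orig_major <- which(!sm$synthetic & sm$y == "good")
  surv <- intersect(orig_major, which(cleaned$kept))
  expect_identical(sm$x[surv, ], d$x[d$y == "good", ][
    match(surv, orig_major), , drop = FALSE])
})

test_that("importance screen normalizes to one and finds a dominant signal", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 240
    x <- random_design(n, 6, seed = seed, prefix = "noise")
    y <- factor(rep(c("good", "poor"), each = n / 2), c("good", "poor"))
    x$signal <- ifelse(y == "poor", 1, 0) + rnorm(n, 0, 0.05)
    scr <- importance_screen(x, y, threshold = 0.05, seed = seed,
                             ntree = 200L, nrounds = 50L)
    expect_equal(sum(scr$rf$importance), 1, tolerance = 1e-9)
    expect_equal(sum(scr$xgb$importance), 1, tolerance = 1e-9)
    expect_true("signal" %in% scr$rf$retained)
    expect_true("signal" %in% scr$xgb$retained)
  }
  # threshold zero retains everything
  set.seed(1)
  x <- random_design(120, 4, seed = 11)
  y <- factor(rep(c("a", "b"), 60))
  scr0 <- importance_screen(x, y, threshold = 0, seed = 1L,
                            ntree = 100L, nrounds = 30L)
  expect_setequal(scr0$rf$retained, colnames(x))
  expect_setequal(scr0$xgb$retained, colnames(x))
})

test_that("candidate-set algebra is exact", {
  sets <- build_candidate_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(sets$D_union, c("a", "b", "c", "d"))
  expect_setequal(sets$D_intersection, c("b", "c"))
  same <- build_candidate_sets(c("x", "y"), c("y", "x"))
  expect_setequal(same$D_union, same$D_intersection)

  set.seed(20)
  for (i in 1:20) {
    d1 <- sample(letters, sample(3:10, 1))
    d2 <- sample(letters, sample(3:10, 1))
    s <- build_candidate_sets(d1, d2)
    expect_equal(s$cardinalities[["D_union"]] +
                   s$cardinalities[["D_intersection"]],
                 s$cardinalities[["D1"]] + s$cardinalities[["D2"]])
    expect_true(all(s$D_intersection %in% s$D1))
    expect_true(all(s$D1 %in% s$D_union))
  }
})

test_that("set evaluation flags a perfectly separating feature and is deterministic", {
  set.seed(6)
  n <- 200
  x <- random_design(n, 3, seed = 6)
  y <- factor(rep(c("good", "poor"), each = n / 2), c("good", "poor"))
  x$oracle <- as.integer(y == "poor")
  sets <- list(with_oracle = c("oracle", "x1"), noise = c("x1", "x2"),
               noise_again = c("x1", "x2"))
  ev <- evaluate_candidate_sets(sets, x, y, seed = 3L, nrounds = 40L,
                                n_boot = 20L)
  expect_equal(ev$sets$with_oracle$test$auc, 1)
  expect_equal(ev$best, "with_oracle")
  # identical sets under the same seed give identical metrics
  expect_equal(ev$sets$noise$test$auc, ev$sets$noise_again$test$auc)
  expect_warning(
    evaluate_candidate_sets(list(ok = c("x1"), empty = character(0)),
                            x, y, seed = 1L, nrounds = 10L, n_boot = 0L),
    "empty candidate set")
})

test_that("SHAP summary satisfies additivity and recovers effect directions", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 300
    x <- data.frame(risk = rnorm(n), protective = rnorm(n), dead = rnorm(n))
    lp <- 1.5 * x$risk - 1.5 * x$protective
    y01 <- rbinom(n, 1, plogis(lp))
    if (length(unique(y01)) < 2) next
    bst <- traumaprog:::fit_xgb(as.matrix(x), y01, nrounds = 60L,
                                seed = seed)
    sh <- shap_summary(bst, x)
    expect_lt(attr(sh, "additivity_error"), 1e-4)
    expect_equal(sh$direction[sh$feature == "risk"], "risk")
    expect_equal(sh$direction[sh$feature == "protective"], "protective")
    # an uninformative feature attributes (almost) nothing
    expect_lt(sh$mean_abs_shap[sh$feature == "dead"],
              min(sh$mean_abs_shap[sh$feature != "dead"]))
    expect_true(all(sh$positive_share >= 0 & sh$positive_share <= 1))
    expect_true(!is.unsorted(rev(sh$mean_abs_shap)))
  }
})

test_that("retained sets are stable across seeds on the default cohort", {
  co <- generate_cohort(cohort_spec(seed = 50L, missing_rate = 0))
  y <- dichotomize_outcome(co$outcome)
  x <- co[c("albumin", "ada", "heart_rate", "hb", "ast", "creatinine",
            "prealbumin", "cholinesterase", "afu", "urea")]
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  sets <- lapply(1:10, function(s) {
    rb <- rebalance(x, y, "smote_enn", seed = s)
    scr <- importance_screen(rb$x, rb$y, seed = s, ntree = 300L,
                             nrounds = 80L)
    union(scr$rf$retained, scr$xgb$retained)
  })
  pair_j <- combn(10, 2, function(ij) jaccard(sets[[ij[1]]], sets[[ij[2]]]))
  expect_gte(mean(pair_j), 0.5)
})

test_that("the EPV gate warns exactly when the rule is violated", {
  expect_warning(epv_check(11, 54), "EPV")
  expect_silent(epv_check(5, 54))
  expect_silent(epv_check(11, 110))
})
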