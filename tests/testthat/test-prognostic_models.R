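logistic_data <- function(n, beta, n_noise = 0L, seed = 1L,
                          intercept = -0.5) {
  set.seed(seed)
  p <- length(beta) + n_noise
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- c(paste0("sig", seq_along(beta)),
                   if (n_noise) paste0("noise", seq_len(n_noise)))
  lp <- intercept + x[, seq_along(beta), drop = FALSE] %*% beta
  y <- rbinom(n, 1, plogis(lp))
  list(x = as.data.frame(x), y = y, beta = beta)
}

test_that("stepwise table reports Wald, Exp(B) and CIs consistently", {
  d <- logistic_data(600, c(0.8, -0.6), n_noise = 2, seed = 3)
  fit <- stepwise_logistic(d$x, d$y)
  tab <- fit$table
  expect_equal(tab$Wald, (tab$B / tab$SE)^2, tolerance = 1e-12)
  expect_equal(tab$ExpB, exp(tab$B), tolerance = 1e-12)
  expect_equal(tab$ci_lower, exp(tab$B - 1.96 * tab$SE), tolerance = 1e-12)
  expect_equal(tab$ci_upper, exp(tab$B + 1.96 * tab$SE), tolerance = 1e-12)
  expect_true(all(tab$ci_lower < tab$ExpB & tab$ExpB < tab$ci_upper))
  expect_true(all(tab$ExpB > 0))
  # the step trace starts at the full model and records AIC per removal
  expect_equal(fit$steps$action[1], "start")
  expect_true(all(fit$steps$p_removed[-1] > fit$alpha_exit))
})

test_that("stepwise keeps strong signals and tends to drop noise", {
  d <- logistic_data(1200, c(1.0, -0.9, 0.8), n_noise = 4, seed = 8)
  fit <- stepwise_logistic(d$x, d$y)
  expect_true(all(paste0("sig", 1:3) %in% fit$retained))
  # recovered coefficients are close to the truth
  b_hat <- fit$table$B[match(paste0("sig", 1:3), fit$table$variable)]
  expect_equal(b_hat, d$beta, tolerance = 0.35)
})

test_that("perfect separation is detected and flagged", {
  x <- data.frame(z = c(rnorm(30, -3), rnorm(30, 3)))
  y <- rep(c(0L, 1L), each = 30)
  expect_warning(fit <- stepwise_logistic(x, y), "separation")
  expect_true(fit$separation)
})

test_that("nomogram point scales span 0-100 and the probability map is monotone", {
  d <- logistic_data(400, c(1.2), seed = 5)
  fit <- stepwise_logistic(d$x, d$y)
  expect_true("sig1" %in% fit$retained)
  nomo <- build_nomogram(fit, d$x, d$y, n_boot = 50L, seed = 2L)
  expect_equal(nomo$points$sig1$max_points, 100, tolerance = 1e-9)
  totals <- seq(0, 100, by = 10)
  probs <- vapply(totals, nomo$total_points_map, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_true(all(probs >= 0 & probs <= 1))

  # several variables: the largest |coef x range| variable takes the 0-100
  d2 <- logistic_data(500, c(1.5, 0.3), seed = 6)
  fit2 <- stepwise_logistic(d2$x, d2$y)
  if (all(c("sig1", "sig2") %in% fit2$retained)) {
    nomo2 <- build_nomogram(fit2, d2$x, d2$y, n_boot = 20L, seed = 3L)
    spans <- vapply(nomo2$points, `[[`, numeric(1), "max_points")
    expect_equal(max(spans), 100, tolerance = 1e-9)
  }
})

test_that("C-index is 1 on a separable fixture and calibration MAE is small when well-specified", {
  x <- data.frame(z = c(rnorm(40, -4), rnorm(40, 4)))
  y <- rep(c(0L, 1L), each = 40)
  fit <- suppressWarnings(stepwise_logistic(x, y))
  nomo <- suppressWarnings(build_nomogram(fit, x, y, n_boot = 30L,
                                          seed = 4L))
  expect_equal(nomo$c_index, 1)

  d <- logistic_data(2000, c(0.9, -0.7), seed = 9)
  fitw <- stepwise_logistic(d$x, d$y)
  nomow <- build_nomogram(fitw, d$x, d$y, n_boot = 150L, seed = 5L)
  expect_lt(nomow$calibration_mae, 0.05)
  expect_error(build_nomogram(
    suppressWarnings(stepwise_logistic(data.frame(c0 = rep(1, 50)),
                                       rbinom(50, 1, 0.5))),
    data.frame(c0 = rep(1, 50)), rbinom(50, 1, 0.5)),
    "zero-range|no retained")
})

test_that("metric panel reproduces an arithmetic oracle on a hand matrix", {
  # confusion matrix [[8,2],[3,7]]: rows = true (neg first), cols = pred
  y_true <- c(rep(0L, 10), rep(1L, 10))
  y_pred <- c(rep(0L, 8), rep(1L, 2), rep(0L, 3), rep(1L, 7))
  score <- seq_along(y_true) / 20
  mp <- metric_panel(y_true, y_pred, score, n_boot = 0L)
  expect_equal(mp$acc, 15 / 20)
  expect_equal(mp$tpr, 7 / 10)
  expect_equal(mp$tnr, 8 / 10)
  expect_equal(mp$pre, 7 / 9)
  expect_equal(mp$f1, 2 * (7 / 9) * 0.7 / ((7 / 9) + 0.7))

  perfect <- metric_panel(rep(c(0L, 1L), each = 50),
                          rep(c(0L, 1L), each = 50),
                          rep(c(0, 1), each = 50), n_boot = 0L)
  for (f in c("acc", "pre", "tpr", "tnr", "f1", "auc"))
    expect_equal(perfect[[f]], 1)

  # no predicted positives: precision undefined -> 0, flagged
  none <- metric_panel(rep(c(0L, 1L), 10), rep(0L, 20), runif(20),
                       n_boot = 0L)
  expect_equal(none$pre, 0)
  expect_false(none$precision_defined)
})

test_that("AUC of label-independent scores concentrates at one half", {
  set.seed(23)
  y <- rbinom(10000, 1, 0.4)
  s <- rnorm(10000)
  expect_equal(auc_rank(y, s), 0.5, tolerance = 0.02)
})

test_that("rank AUC agrees with the pROC reference implementation", {
  set.seed(31)
  for (i in 1:5) {
    y <- rbinom(150, 1, 0.3)
    s <- rnorm(150) + y
    expect_equal(auc_rank(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("macro metrics reduce to plain binary metrics in the symmetric balanced case", {
  y <- factor(rep(c("a", "b"), each = 30))
  pred <- factor(c(rep("a", 24), rep("b", 6), rep("b", 24), rep("a", 6)),
                 levels = c("a", "b"))
  score <- cbind(a = as.numeric(pred == "a"), b = as.numeric(pred == "b"))
  macro <- metric_panel(y, pred, score, averaging = "macro", n_boot = 0L)
  plain <- metric_panel(as.integer(y == "b"), as.integer(pred == "b"),
                        score[, "b"], n_boot = 0L)
  expect_equal(macro$f1, plain$f1, tolerance = 1e-12)
  expect_equal(macro$acc, plain$acc, tolerance = 1e-12)
})

test_that("overfit gap reproduces differences and the flag rule exactly", {
  expect_equal(overfit_gap(0.9, 0.9)$gap, 0)
  g <- overfit_gap(c(m = 0.985), c(m = 0.768))
  expect_equal(round(g$gap, 3), 0.217)
  expect_true(g$flagged)
  gr <- overfit_gap(c(a = 0.80, b = 0.96), c(a = 0.70, b = 0.80))
  expect_equal(gr$flagged, c(FALSE, TRUE))
  expect_equal(overfit_gap(0.9, 0.8, threshold = 0.09)$flagged, TRUE)
})

test_that("benchmark is deterministic and sane on leaking and random labels", {
  set.seed(40)
  n <- 150
  x <- random_design(n, 4, seed = 40)
  y <- factor(rep(c("good", "poor"), length.out = n), c("good", "poor"))
  cfg <- bench_config(models = c("rf", "xgb"), n_boot = 0L, seed = 7L)

  # a label-leaking feature drives test AUC to ~1 for every model
  x_leak <- x
  x_leak$leak <- as.integer(y == "poor")
  b_leak <- run_benchmark(x_leak, y, cfg)
  for (m in names(b_leak$models))
    expect_gt(b_leak$models[[m]]$test$auc, 0.98)

  # random labels give chance-level test AUC
  aucs <- unlist(lapply(1:3, function(s) {
    set.seed(s + 100)
    y_r <- factor(sample(c("good", "poor"), n, TRUE), c("good", "poor"))
    br <- run_benchmark(x, y_r, bench_config(models = "xgb", n_boot = 0L,
                                             seed = s))
    br$models$xgb$test$auc
  }))
  expect_true(all(aucs > 0.35 & aucs < 0.65))

  # determinism under an identical config and seed
  r1 <- run_benchmark(x_leak, y, cfg)
  r2 <- run_benchmark(x_leak, y, cfg)
  expect_equal(r1$models$rf$test$auc, r2$models$rf$test$auc)
  expect_equal(r1$models$xgb$train, r2$models$xgb$train)

  # a missing backend is logged, never silent
  b_skip <- run_benchmark(x, y, bench_config(models = c("xgb", "lightgbm"),
                                             n_boot = 0L, seed = 1L))
  expect_true(any(grepl("lightgbm", b_skip$skipped)))
  expect_false("lightgbm" %in% names(b_skip$models))
})

test_that("exp(B) arithmetic matches reference coefficients to print precision", {
  ref <- table7_reference()
  keep <- ref$variable %in% c("ODS", "HR", "ALB", "ADA")
  expect_equal(round(exp(ref$B[keep]), 3), ref$ExpB[keep])
})
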