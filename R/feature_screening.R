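knn_indices <- function(X, query_rows, pool_rows, k) {
  # scaled Euclidean k-NN of each query row among pool rows (self excluded)
  vapply(query_rows, function(i) {
    d <- sqrt(colSums((t(X[pool_rows, , drop = FALSE]) - X[i, ])^2))
    d[pool_rows == i] <- Inf
    pool_rows[order(d)[seq_len(k)]]
  }, integer(k))
}

scale_for_knn <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, sd_, "/")
}

#' SMOTE oversampling of the minority class
#'
#' Each synthetic point is a convex combination of a minority sample and one
#' of its `k` nearest minority neighbours (uniform interpolation weight), so
#' every synthetic point lies on a segment between two original minority
#' points. Oversamples until the classes are balanced.
#'
#' @param x Numeric feature matrix/data.frame.
#' @param y Binary labels (factor, second level = minority by count).
#' @param k Number of minority neighbours.
#' @param seed Optional seed.
#' @return List `x` (matrix incl. synthetic rows), `y`, `synthetic`
#'   (logical row marker).
#' @export
smote <- function(x, y, k = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.factor(y)
  tab <- table(y)
  min_cl <- names(tab)[which.min(tab)]
  maj_cl <- names(tab)[which.max(tab)]
  n_new <- tab[[maj_cl]] - tab[[min_cl]]
  min_idx <- which(y == min_cl)
  if (length(min_idx) <= k)
    stop("minority class (", length(min_idx),
         ") must exceed the neighbour count k = ", k)
  if (n_new == 0L)
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  Z <- scale_for_knn(x)
  nn <- knn_indices(Z, min_idx, min_idx, k)   # k x n_min
  base <- sample(seq_along(min_idx), n_new, replace = TRUE)
  pick <- vapply(base, function(b) nn[sample.int(k, 1L), b], integer(1))
  lam <- stats::runif(n_new)
  synth <- x[min_idx[base], , drop = FALSE] * (1 - lam) +
    x[pick, , drop = FALSE] * lam
  list(x = rbind(x, synth),
       y = factor(c(as.character(y), rep(min_cl, n_new)), levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_new)),
       parents = cbind(a = min_idx[base], b = pick, lambda = lam))
}

#' Edited nearest neighbours cleaning
#'
#' Removes every sample whose label disagrees with the majority vote of its
#' `k` nearest neighbours. Rows are only ever deleted, never edited.
#'
#' @inheritParams smote
#' @param k Neighbourhood size for the vote.
#' @return List `x`, `y`, `kept` (logical over input rows).
#' @export
enn <- function(x, y, k = 3L) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.factor(y)
  Z <- scale_for_knn(x)
  all_rows <- seq_len(nrow(x))
  nn <- knn_indices(Z, all_rows, all_rows, k)  # k x n
  keep <- vapply(all_rows, function(i) {
    votes <- table(y[nn[, i]])
    names(votes)[which.max(votes)] == as.character(y[i])
  }, logical(1))
  list(x = x[keep, , drop = FALSE], y = droplevels(y[keep]) , kept = keep)
}

#' Rebalance a binary training set
#'
#' `smote_enn` applies SMOTE oversampling followed by ENN cleaning (the
#' combination used for the binary prognosis task); `smote` stops after
#' oversampling; `none` is the identity.
#'
#' @param x Numeric feature matrix/data.frame.
#' @param y Binary labels.
#' @param method One of `"smote_enn"`, `"smote"`, `"none"`.
#' @param smote_k,enn_k Neighbour counts.
#' @param seed Seed for the synthetic sampling.
#' @return List of class `resample_result`: `x`, `y`, `method`,
#'   `counts_before`, `counts_after`, `ratio_before`, `ratio_after`, `seed`.
#' @export
rebalance <- function(x, y, method = c("smote_enn", "smote", "none"),
                      smote_k = 5L, enn_k = 3L, seed = 1L) {
  method <- match.arg(method)
  y <- as.factor(y)
  before <- table(y)
  if (length(before) != 2L || any(before == 0L))
    stop("both classes must be present")
  if (method == "none") {
    out <- list(x = as.matrix(x), y = y)
  } else {
    sm <- smote(x, y, k = smote_k, seed = seed)
    out <- if (method == "smote") sm else {
      cleaned <- enn(sm$x, sm$y, k = enn_k)
      cleaned
    }
  }
  after <- table(out$y)
  structure(list(x = out$x, y = out$y, method = method,
                 counts_before = as.vector(before),
                 counts_after = as.vector(after),
                 ratio_before = max(before) / min(before),
                 ratio_after = max(after) / min(after),
                 seed = seed),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("rebalance[%s]: %s -> %s (ratio %.2f -> %.2f)\n", x$method,
              paste(x$counts_before, collapse = ":"),
              paste(x$counts_after, collapse = ":"),
              x$ratio_before, x$ratio_after))
  invisible(x)
}

fit_xgb <- function(x, y01, params = list(), nrounds = 200L, seed = 1L) {
  set.seed(seed)
  defaults <- list(objective = "binary:logistic", max_depth = 6,
                   min_child_weight = 3, eta = 0.05, gamma = 0.1,
                   subsample = 0.8, nthread = 1)
  params <- utils::modifyList(defaults, params)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y01)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

#' Tree-ensemble feature-importance screen
#'
#' Fits a random forest (impurity importance) and a gradient-boosted tree
#' model (gain importance), normalizes each algorithm's importances to sum
#' to 1, and retains the features at or above `threshold`.
#'
#' @param x Numeric feature matrix/data.frame.
#' @param y Binary labels.
#' @param threshold Importance share cut-off (default 5%).
#' @param seed Seed used for both ensembles.
#' @param ntree Random-forest tree count.
#' @param nrounds Boosting rounds.
#' @return List of class `importance_screen`: per algorithm normalized
#'   `importance` (named, sums to 1) and `retained`; plus `threshold`,
#'   `seed`.
#' @export
importance_screen <- function(x, y, threshold = 0.05, seed = 1L,
                              ntree = 500L, nrounds = 200L) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("need at least 2 candidate features")
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L) stop("labels must be binary")

  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = ntree, importance = FALSE)
  imp_rf <- rf$importance[, "MeanDecreaseGini"]
  imp_rf <- imp_rf / sum(imp_rf)

  y01 <- as.integer(y == levels(y)[2L])
  bst <- fit_xgb(x, y01, nrounds = nrounds, seed = seed)
  imp_tab <- xgboost::xgb.importance(model = bst)
  imp_xgb <- stats::setNames(rep(0, ncol(x)), colnames(x))
  imp_xgb[imp_tab$Feature] <- imp_tab$Gain
  imp_xgb <- imp_xgb / sum(imp_xgb)

  structure(list(
    rf = list(importance = sort(imp_rf, decreasing = TRUE),
              retained = names(imp_rf)[imp_rf >= threshold]),
    xgb = list(importance = sort(imp_xgb, decreasing = TRUE),
               retained = names(imp_xgb)[imp_xgb >= threshold]),
    threshold = threshold, seed = seed),
    class = "importance_screen")
}

#' Candidate feature sets from two screening runs
#'
#' D1 = first (random-forest) retained set, D2 = second (boosted-tree)
#' retained set, plus their union and intersection.
#'
#' @param d1,d2 Character vectors of feature names.
#' @return List of class `candidate_sets` with `D1`, `D2`, `D_union`,
#'   `D_intersection` and `cardinalities`.
#' @export
build_candidate_sets <- function(d1, d2) {
  d1 <- unique(as.character(d1)); d2 <- unique(as.character(d2))
  u <- union(d1, d2); i <- intersect(d1, d2)
  structure(list(D1 = d1, D2 = d2, D_union = u, D_intersection = i,
                 cardinalities = c(D1 = length(d1), D2 = length(d2),
                                   D_union = length(u),
                                   D_intersection = length(i))),
            class = "candidate_sets")
}

#' Evaluate candidate feature sets with a boosted-tree learner
#'
#' For each candidate set: stratified 8:2 train/test split, 5-fold
#' cross-validated AUC on the training part, then a fit on the full training
#' part evaluated on both splits with the full metric panel. The best set is
#' flagged by test AUC. Empty sets are skipped with a warning.
#'
#' @param sets A [build_candidate_sets()] result (or named list of character
#'   vectors).
#' @param x Feature data.frame (superset of all candidate features).
#' @param y Binary labels.
#' @param seed Seed controlling the shared split and fits.
#' @param nrounds Boosting rounds.
#' @param n_boot Bootstrap replicates for AUC CIs.
#' @return List of class `set_evaluation`: per-set `cv_auc`, `train`
#'   and `test` metric panels; `best` (set name by test AUC); `split`.
#' @export
evaluate_candidate_sets <- function(sets, x, y, seed = 1L, nrounds = 200L,
                                    n_boot = 200L) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  y01 <- as.integer(y == levels(y)[2L])
  set_list <- if (inherits(sets, "candidate_sets"))
    sets[c("D1", "D2", "D_union", "D_intersection")] else sets

  fold_outer <- stratified_folds(y, k = 5L, seed = derive_seed(seed, "split"))
  test_idx <- which(fold_outer == 1L)   # stratified 1/5 holds out ~20%
  train_idx <- setdiff(seq_along(y), test_idx)

  results <- list()
  for (nm in names(set_list)) {
    feats <- set_list[[nm]]
    if (!length(feats)) { warning("empty candidate set: ", nm); next }
    missing_feats <- setdiff(feats, colnames(x))
    if (length(missing_feats))
      stop("features absent from data: ", paste(missing_feats, collapse = ", "))
    xtr <- x[train_idx, feats, drop = FALSE]
    ytr <- y01[train_idx]
    cv_fold <- stratified_folds(ytr, k = 5L,
                                seed = derive_seed(seed, paste0("cv_", nm)))
    cv_auc <- vapply(1:5, function(f) {
      fit <- fit_xgb(xtr[cv_fold != f, , drop = FALSE], ytr[cv_fold != f],
                     nrounds = nrounds, seed = derive_seed(seed, "cvfit"))
      pred <- stats::predict(fit, as.matrix(xtr[cv_fold == f, , drop = FALSE]))
      if (length(unique(ytr[cv_fold == f])) < 2L) return(NA_real_)
      auc_rank(ytr[cv_fold == f], pred)
    }, numeric(1))
    fit <- fit_xgb(xtr, ytr, nrounds = nrounds,
                   seed = derive_seed(seed, "finalfit"))
    p_tr <- stats::predict(fit, as.matrix(xtr))
    p_te <- stats::predict(fit, as.matrix(x[test_idx, feats, drop = FALSE]))
    results[[nm]] <- list(
      features = feats,
      cv_auc = mean(cv_auc, na.rm = TRUE),
      train = metric_panel(ytr, as.integer(p_tr >= 0.5), p_tr,
                           n_boot = n_boot,
                           seed = derive_seed(seed, "boot_tr")),
      test = metric_panel(y01[test_idx], as.integer(p_te >= 0.5), p_te,
                          n_boot = n_boot,
                          seed = derive_seed(seed, "boot_te")),
      model = fit)
  }
  if (!length(results)) stop("all candidate sets were empty")
  test_auc <- vapply(results, function(r) r$test$auc, numeric(1))
  structure(list(sets = results, best = names(which.max(test_auc)),
                 split = list(train = train_idx, test = test_idx),
                 seed = seed),
            class = "set_evaluation")
}

#' SHAP-style attribution summary for a boosted-tree model
#'
#' Uses exact TreeSHAP contributions (`predcontrib`) from the fitted
#' gradient-boosted model: per feature the mean absolute SHAP value, the
#' share of positive SHAP values, and a direction label (`risk` when higher
#' feature values push predictions up, `protective` otherwise, judged by the
#' correlation between feature value and its attribution).
#'
#' @param model A fitted `xgb.Booster` (binary logistic).
#' @param x Feature data used for the attributions (columns must match the
#'   model's training features).
#' @return Data frame of class `shap_summary`, sorted by mean |SHAP|:
#'   `feature`, `mean_abs_shap`, `mean_shap`, `positive_share`, `direction`.
#'   Attribute `base_value` carries the model bias; attribute `additivity_ok`
#'   reports max |rowSum + base - margin|.
#' @export
shap_summary <- function(model, x) {
  x <- as.matrix(x)
  contrib <- stats::predict(model, xgboost::xgb.DMatrix(x),
                            predcontrib = TRUE)
  contrib <- as.matrix(contrib)
  bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1L]
  base <- contrib[, bias_col]
  sv <- contrib[, setdiff(colnames(contrib), bias_col), drop = FALSE]
  margin <- stats::predict(model, xgboost::xgb.DMatrix(x),
                           outputmargin = TRUE)
  add_err <- max(abs(rowSums(sv) + base - margin))
  dirs <- vapply(colnames(sv), function(nm) {
    if (stats::sd(x[, nm]) == 0 || stats::sd(sv[, nm]) == 0) return("none")
    if (stats::cor(x[, nm], sv[, nm]) >= 0) "risk" else "protective"
  }, character(1))
  out <- data.frame(feature = colnames(sv),
                    mean_abs_shap = colMeans(abs(sv)),
                    mean_shap = colMeans(sv),
                    positive_share = colMeans(sv > 0),
                    direction = dirs, row.names = NULL)
  out <- out[order(-out$mean_abs_shap), ]
  rownames(out) <- NULL
  attr(out, "base_value") <- mean(base)
  attr(out, "additivity_error") <- add_err
  class(out) <- c("shap_summary", "data.frame")
  out
}

#' Events-per-variable gate
#'
#' Warns when the retained feature count would need more than
#' `events / per_variable` variables, i.e. when
#' `n_features * per_variable > n_events`.
#'
#' @param n_features Number of candidate model variables.
#' @param n_events Positive-class event count.
#' @param per_variable Required events per variable (rule of thumb 10).
#' @return Logical: `TRUE` when the rule is satisfied (invisibly); otherwise
#'   a warning is raised and `FALSE` returned.
#' @export
epv_check <- function(n_features, n_events, per_variable = 10) {
  ok <- n_features * per_variable <= n_events
  if (!ok)
    warning(sprintf(
      "EPV rule violated: %d features x %g events-per-variable > %d events",
      n_features, per_variable, n_events))
  invisible(ok)
}
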