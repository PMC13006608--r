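binary_counts <- function(y_true, y_pred) {
  tp <- sum(y_pred == 1L & y_true == 1L)
  tn <- sum(y_pred == 0L & y_true == 0L)
  fp <- sum(y_pred == 1L & y_true == 0L)
  fn <- sum(y_pred == 0L & y_true == 1L)
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

binary_metrics <- function(y_true, y_pred) {
  ct <- binary_counts(y_true, y_pred)
  acc <- (ct["tp"] + ct["tn"]) / sum(ct)
  pre_defined <- (ct["tp"] + ct["fp"]) > 0
  pre <- if (pre_defined) ct["tp"] / (ct["tp"] + ct["fp"]) else 0
  tpr <- if ((ct["tp"] + ct["fn"]) > 0) ct["tp"] / (ct["tp"] + ct["fn"]) else 0
  tnr <- if ((ct["tn"] + ct["fp"]) > 0) ct["tn"] / (ct["tn"] + ct["fp"]) else 0
  f1 <- if ((pre + tpr) > 0) 2 * pre * tpr / (pre + tpr) else 0
  list(acc = unname(acc), pre = unname(pre), tpr = unname(tpr),
       tnr = unname(tnr), f1 = unname(f1),
       precision_defined = unname(pre_defined))
}

#' Classification metric panel
#'
#' Confusion-matrix metrics (ACC, PRE, TPR, TNR, F1) plus AUC with a
#' stratified-bootstrap 95% CI. Binary panels treat the second factor level
#' (or 1) as positive; multiclass panels macro-average one-vs-rest metrics
#' and also report the micro-average AUC used for pooled ROC display.
#' Undefined precision (no predicted positives) is reported as 0 and
#' flagged.
#'
#' @param y_true True labels (binary 0/1 or a factor).
#' @param y_pred Predicted labels, same coding.
#' @param y_score For binary: numeric score for the positive class. For
#'   multiclass: matrix of class scores (columns named by class).
#' @param averaging `"binary"`, `"macro"` (adds micro AUC) for multiclass.
#' @param n_boot Bootstrap replicates for the AUC CI (0 disables).
#' @param seed Seed for the bootstrap.
#' @return List of class `metric_panel` with `acc`, `pre`, `tpr`, `tnr`,
#'   `f1`, `auc`, `auc_ci`, `confusion`, and for multiclass `per_class` and
#'   `auc_micro`.
#' @export
metric_panel <- function(y_true, y_pred, y_score,
                         averaging = c("binary", "macro"),
                         n_boot = 1000L, seed = NULL) {
  averaging <- match.arg(averaging)
  if (averaging == "binary") {
    yt <- as_binary01(y_true); yp <- as_binary01(y_pred)
    stopifnot(length(yt) == length(yp), length(yt) == length(y_score))
    m <- binary_metrics(yt, yp)
    ci <- auc_ci(yt, y_score, n_boot = n_boot, seed = seed)
    out <- list(acc = m$acc, pre = m$pre, tpr = m$tpr, tnr = m$tnr,
                f1 = m$f1, auc = unname(ci["auc"]),
                auc_ci = unname(ci[c("lower", "upper")]),
                precision_defined = m$precision_defined,
                confusion = table(true = yt, pred = yp),
                averaging = "binary")
  } else {
    yt <- as.factor(y_true)
    yp <- factor(y_pred, levels = levels(yt))
    classes <- levels(yt)
    stopifnot(is.matrix(y_score) || is.data.frame(y_score))
    y_score <- as.matrix(y_score)
    if (is.null(colnames(y_score))) colnames(y_score) <- classes
    per_class <- lapply(classes, function(cl) {
      yb <- as.integer(yt == cl)
      pb <- as.integer(yp == cl)
      m <- binary_metrics(yb, pb)
      m$auc <- if (length(unique(yb)) == 2L) auc_rank(yb, y_score[, cl]) else NA
      m
    })
    names(per_class) <- classes
    avg <- function(field) mean(vapply(per_class, function(m)
      as.numeric(m[[field]]), numeric(1)), na.rm = TRUE)
    # micro AUC: pool all (class, sample) one-vs-rest pairs
    yb_all <- as.integer(unlist(lapply(classes, function(cl) yt == cl)))
    sc_all <- as.numeric(y_score[, classes])
    micro <- auc_rank(yb_all, sc_all)
    macro_auc_boot <- function(idx) {
      mean(vapply(classes, function(cl) {
        yb <- as.integer(yt[idx] == cl)
        if (length(unique(yb)) < 2L) return(NA_real_)
        auc_rank(yb, y_score[idx, cl])
      }, numeric(1)), na.rm = TRUE)
    }
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 1L) {
      if (!is.null(seed)) set.seed(seed)
      strata <- split(seq_along(yt), yt)
      reps <- vapply(seq_len(n_boot), function(b) {
        idx <- unlist(lapply(strata, sample, replace = TRUE))
        macro_auc_boot(idx)
      }, numeric(1))
      ci <- unname(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE))
    }
    out <- list(acc = mean(yp == yt), pre = avg("pre"), tpr = avg("tpr"),
                tnr = avg("tnr"), f1 = avg("f1"), auc = avg("auc"),
                auc_ci = ci, auc_micro = micro, per_class = per_class,
                confusion = table(true = yt, pred = yp),
                averaging = "macro")
  }
  structure(out, class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, digits = 3, ...) {
  cat(sprintf("%s panel: ACC %.3f PRE %.3f TPR %.3f TNR %.3f F1 %.3f AUC %.3f",
              x$averaging, x$acc, x$pre, x$tpr, x$tnr, x$f1, x$auc))
  if (all(is.finite(x$auc_ci)))
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$auc_ci[1], x$auc_ci[2]))
  cat("\n")
  invisible(x)
}

#' Train-test overfitting gap report
#'
#' Per-model difference between training and test AUC; models whose gap
#' exceeds `threshold` are flagged as candidates for early stopping and L2
#' regularization.
#'
#' @param train_auc,test_auc Named numeric vectors (same names) or single
#'   values.
#' @param threshold Flagging threshold on the gap.
#' @return Data frame: `model`, `train_auc`, `test_auc`, `gap`, `flagged`.
#' @export
overfit_gap <- function(train_auc, test_auc, threshold = 0.15) {
  stopifnot(length(train_auc) == length(test_auc))
  nm <- names(train_auc) %||% paste0("model", seq_along(train_auc))
  gap <- as.numeric(train_auc) - as.numeric(test_auc)
  data.frame(model = nm, train_auc = as.numeric(train_auc),
             test_auc = as.numeric(test_auc), gap = gap,
             flagged = gap > threshold, row.names = NULL)
}
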