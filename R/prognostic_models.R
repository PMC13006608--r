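#' Backward stepwise logistic regression
#'
#' Starts from the full binomial GLM and repeatedly removes the variable
#' with the largest likelihood-ratio p-value while that p-value exceeds
#' `alpha_exit` (ties broken toward the removal yielding the lowest AIC).
#' The step trace records AIC at every accepted step. Perfect separation is
#' detected (fitted probabilities collapsing to 0/1) and flagged; a
#' penalized fit is suggested rather than silently reported.
#'
#' @param data Data frame of predictors (numeric or factor).
#' @param y Binary outcome (0/1, logical, or two-level factor with the
#'   positive class second).
#' @param alpha_entry Entry threshold (recorded; backward-only search).
#' @param alpha_exit Removal threshold on the likelihood-ratio p-value.
#' @return Object of class `stepwise_fit`: `table` (B, SE, Wald, p, ExpB,
#'   CI bounds per retained variable), `intercept`, `steps` (trace with AIC),
#'   `model` (the final `glm`), `separation` flag.
#' @export
stepwise_logistic <- function(data, y, alpha_entry = 0.05, alpha_exit = 0.10) {
  data <- as.data.frame(data)
  y01 <- as_binary01(y)
  stopifnot(nrow(data) == length(y01))
  work <- cbind(data, .y = y01)

  fit_on <- function(vars) {
    fml <- if (length(vars))
      stats::reformulate(vars, response = ".y") else .y ~ 1
    stats::glm(fml, family = stats::binomial(), data = work)
  }

  vars <- colnames(data)
  fit <- fit_on(vars)
  p_hat <- stats::fitted(fit)
  separation <- any(p_hat > 1 - 1e-8) && any(p_hat < 1e-8) &&
    all(abs(p_hat - y01) < 1e-8)
  if (separation)
    warning("perfect separation detected; coefficients are unreliable - ",
            "consider a penalized (ridge/lasso) fit")

  steps <- data.frame(step = 0L, action = "start", variable = NA_character_,
                      aic = stats::AIC(fit), p_removed = NA_real_,
                      stringsAsFactors = FALSE)
  step_no <- 0L
  repeat {
    if (!length(vars)) break
    d1 <- stats::drop1(fit, test = "LRT")
    cand <- d1[-1L, , drop = FALSE]             # drop the <none> row
    p_vals <- cand[["Pr(>Chi)"]]
    p_vals[is.na(p_vals)] <- 1   # aliased/constant terms contribute nothing
    aics <- cand[["AIC"]]
    worst_p <- max(p_vals)
    if (worst_p <= alpha_exit) break
    tied <- which(p_vals >= worst_p - 1e-12)
    pick <- tied[which.min(aics[tied])]
    removed <- rownames(cand)[pick]
    vars <- setdiff(vars, removed)
    fit <- fit_on(vars)
    step_no <- step_no + 1L
    steps <- rbind(steps, data.frame(
      step = step_no, action = "remove", variable = removed,
      aic = stats::AIC(fit), p_removed = worst_p, stringsAsFactors = FALSE))
  }

  sm <- summary(fit)$coefficients
  b <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  tab <- data.frame(
    variable = rownames(sm), B = b, SE = se, Wald = (b / se)^2,
    p = sm[, "Pr(>|z|)"], ExpB = exp(b),
    ci_lower = exp(b - 1.96 * se), ci_upper = exp(b + 1.96 * se),
    row.names = NULL)
  intercept <- tab[tab$variable == "(Intercept)", ]
  tab <- tab[tab$variable != "(Intercept)", ]
  structure(list(table = tab, intercept = intercept, steps = steps,
                 model = fit, retained = vars, separation = separation,
                 alpha_entry = alpha_entry, alpha_exit = alpha_exit),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("backward stepwise logistic fit (", nrow(x$steps) - 1L, "removals, ",
      "final AIC ", round(utils::tail(x$steps$aic, 1L), 1), ")\n", sep = "")
  if (x$separation) cat("  WARNING: perfect separation flagged\n")
  print(transform(x$table, B = round(B, 3), SE = round(SE, 3),
                  Wald = round(Wald, 2), p = signif(p, 3),
                  ExpB = round(ExpB, 3), ci_lower = round(ci_lower, 3),
                  ci_upper = round(ci_upper, 3)))
  invisible(x)
}

#' Nomogram representation of a logistic model
#'
#' Maps each retained variable's contribution onto a 0-100 point scale: the
#' variable with the largest |coefficient x observed range| spans the full
#' scale, the others proportionally less. Total points map monotonically to
#' predicted probability. Internal validation reports the C-index (rank AUC
#' of the linear predictor) with a bootstrap CI and a bootstrap calibration
#' curve: each replicate refits the model on a resample, predicts the
#' original data, and the mean absolute error between binned predicted and
#' observed event rates is averaged over replicates.
#'
#' @param fit A [stepwise_logistic()] result.
#' @param data The data the model was fit on (for observed ranges).
#' @param y The binary outcome used in the fit.
#' @param n_boot Bootstrap replicates (study default 1000).
#' @param bins Calibration bins.
#' @param seed Seed for the bootstrap.
#' @return Object of class `nomogram`: `points` (per-variable scale),
#'   `total_points_map` (total points to probability), `c_index` (+ CI),
#'   `calibration_mae`.
#' @export
build_nomogram <- function(fit, data, y, n_boot = 1000L, bins = 10L,
                           seed = 1L) {
  stopifnot(inherits(fit, "stepwise_fit"))
  vars <- fit$retained
  if (!length(vars)) stop("no retained variables to build a nomogram from")
  y01 <- as_binary01(y)
  data <- as.data.frame(data)

  coefs <- stats::coef(fit$model)
  b0 <- coefs["(Intercept)"]
  b <- coefs[vars]
  rng <- lapply(vars, function(v) range(as.numeric(data[[v]]), na.rm = TRUE))
  names(rng) <- vars
  span <- vapply(vars, function(v) abs(b[v]) * diff(rng[[v]]), numeric(1))
  if (any(span == 0)) stop("zero-range variable(s): ",
                           paste(vars[span == 0], collapse = ", "))
  ppu <- 100 / max(span)                     # points per unit of |lp| change

  points <- lapply(vars, function(v) {
    lo <- rng[[v]][1]; hi <- rng[[v]][2]
    # low end of the scale = value minimizing the linear predictor
    origin <- if (b[v] >= 0) lo else hi
    list(variable = v, coefficient = unname(b[v]), range = c(lo, hi),
         points_at = function(x) abs(b[v]) * abs(x - origin) * ppu,
         max_points = unname(span[v] * ppu))
  })
  names(points) <- vars

  lp_at_origin <- b0 + sum(vapply(vars, function(v) {
    b[v] * (if (b[v] >= 0) rng[[v]][1] else rng[[v]][2])
  }, numeric(1)))
  total_points_map <- function(total) stats::plogis(lp_at_origin + total / ppu)

  lp <- as.numeric(stats::predict(fit$model, type = "link"))
  ci <- auc_ci(y01, lp, n_boot = n_boot, seed = seed)

  # bootstrap calibration
  set.seed(derive_seed(seed, "calibration"))
  fml <- stats::formula(fit$model)
  work <- cbind(data, .y = y01)
  maes <- vapply(seq_len(max(n_boot, 1L)), function(bb) {
    idx <- sample.int(nrow(work), replace = TRUE)
    bfit <- suppressWarnings(
      stats::glm(fml, family = stats::binomial(), data = work[idx, ]))
    p <- stats::predict(bfit, newdata = work, type = "response")
    br <- unique(stats::quantile(p, seq(0, 1, length.out = bins + 1)))
    g <- cut(p, br, include.lowest = TRUE)
    mean(abs(tapply(p, g, mean) - tapply(y01, g, mean)), na.rm = TRUE)
  }, numeric(1))

  structure(list(points = points, total_points_map = total_points_map,
                 points_per_unit = ppu,
                 c_index = unname(ci["auc"]),
                 c_index_ci = unname(ci[c("lower", "upper")]),
                 calibration_mae = mean(maes), n_boot = n_boot),
            class = "nomogram")
}

#' @export
print.nomogram <- function(x, ...) {
  cat("nomogram:", length(x$points), "variables\n")
  for (p in x$points)
    cat(sprintf("  %-20s beta=%7.3f  0-%.0f points over [%g, %g]\n",
                p$variable, p$coefficient, p$max_points,
                p$range[1], p$range[2]))
  cat(sprintf("  C-index %.3f (95%% CI %.3f-%.3f), calibration MAE %.3f\n",
              x$c_index, x$c_index_ci[1], x$c_index_ci[2],
              x$calibration_mae))
  invisible(x)
}

#' Benchmark configuration
#'
#' @param models Model names; available backends: `l1_logistic`,
#'   `l2_logistic`, `svm_rbf`, `rf`, `xgb`. `lightgbm`,
#'   `ga_tabtransformer_rf` and `ga_tabtransformer_xgb` are listed for
#'   completeness but have no backend in this stack and are skipped with a
#'   log entry.
#' @param task `"binary"` or `"multiclass"`.
#' @param outer_folds Outer stratified folds (the held-out fold plays the
#'   20% test role of an 8:2 split).
#' @param tuner Inner hyperparameter search: `"none"` uses the fixed
#'   settings, `"ga"` runs the genetic tuner seeded at them, `"grid"` a small
#'   grid.
#' @param rebalance_method Training-fold rebalancing for the binary task.
#' @param ga_pop,ga_generations Genetic-tuner budget.
#' @param n_boot Bootstrap replicates for AUC CIs.
#' @param seed Global benchmark seed.
#' @return List of class `bench_config`.
#' @export
bench_config <- function(models = c("l1_logistic", "l2_logistic", "svm_rbf",
                                    "rf", "xgb"),
                         task = c("binary", "multiclass"),
                         outer_folds = 5L,
                         tuner = c("none", "ga", "grid"),
                         rebalance_method = "none",
                         ga_pop = 8L, ga_generations = 5L,
                         n_boot = 200L, seed = 1L) {
  structure(list(models = models, task = match.arg(task),
                 outer_folds = as.integer(outer_folds),
                 tuner = match.arg(tuner),
                 rebalance_method = rebalance_method,
                 ga_pop = as.integer(ga_pop),
                 ga_generations = as.integer(ga_generations),
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "bench_config")
}

# ---- model backends -------------------------------------------------------
# each backend: fit(x, y, seed, params) -> object; score(object, x) ->
#   binary: numeric positive-class score; multiclass: matrix of class scores

xgb_tuned_params <- function(x, y01, tuner, cfg, seed) {
  fixed <- list(eta = 0.05, max_depth = 6, nrounds = 200)
  if (tuner == "none") return(fixed)
  eval_par <- function(par) {
    # par: log10(eta), depth, trees
    fold <- stratified_folds(y01, 3L, seed = derive_seed(seed, "inner"))
    mean(vapply(1:3, function(f) {
      fit <- fit_xgb(x[fold != f, , drop = FALSE], y01[fold != f],
                     params = list(eta = 10^par[1],
                                   max_depth = as.integer(par[2])),
                     nrounds = as.integer(par[3]),
                     seed = derive_seed(seed, "innerfit"))
      p <- stats::predict(fit, as.matrix(x[fold == f, , drop = FALSE]))
      if (length(unique(y01[fold == f])) < 2L) return(NA_real_)
      auc_rank(y01[fold == f], p)
    }, numeric(1)), na.rm = TRUE)
  }
  if (tuner == "ga") {
    res <- ga_optimize(eval_par,
                       lower = c(log10(0.01), 3, 100),
                       upper = c(log10(0.3), 8, 400),
                       integer = c(FALSE, TRUE, TRUE),
                       pop_size = cfg$ga_pop,
                       generations = cfg$ga_generations,
                       seed = derive_seed(seed, "ga"),
                       init = matrix(c(log10(0.05), 6, 200), nrow = 1))
    list(eta = 10^res$par[1], max_depth = as.integer(res$par[2]),
         nrounds = as.integer(res$par[3]))
  } else {  # small grid around the fixed values
    grid <- expand.grid(eta = c(0.05, 0.1), max_depth = c(4, 6),
                        nrounds = c(100, 200))
    sc <- apply(grid, 1L, function(g)
      eval_par(c(log10(g[["eta"]]), g[["max_depth"]], g[["nrounds"]])))
    g <- grid[which.max(sc), ]
    list(eta = g$eta, max_depth = as.integer(g$max_depth),
         nrounds = as.integer(g$nrounds))
  }
}

model_backends <- function(task, tuner, cfg) {
  multi <- task == "multiclass"
  glmnet_backend <- function(alpha) list(
    fit = function(x, y, seed, ...) {
      set.seed(seed)
      fam <- if (multi) "multinomial" else "binomial"
      cv <- glmnet::cv.glmnet(as.matrix(x), y, family = fam, alpha = alpha,
                              nfolds = 5)
      cv
    },
    score = function(obj, x) {
      p <- stats::predict(obj, as.matrix(x), s = "lambda.min",
                          type = "response")
      if (multi) p[, , 1L] else as.numeric(p)
    })
  backends <- list(
    l1_logistic = glmnet_backend(1),
    l2_logistic = glmnet_backend(0),
    svm_rbf = list(
      fit = function(x, y, seed, ...) {
        set.seed(seed)
        fit <- e1071::svm(as.matrix(x), as.factor(y), kernel = "radial",
                          cost = 1, gamma = 0.1, probability = TRUE,
                          class.weights = "inverse", tolerance = 1e-3)
        # e1071's Platt probabilities can come out label-flipped (a known
        # libsvm quirk tied to internal label order); orient once against
        # the training labels -- training data only, so no leakage
        flip <- FALSE
        if (!multi) {
          pr <- attr(stats::predict(fit, as.matrix(x), probability = TRUE),
                     "probabilities")
          pos <- levels(as.factor(y))[2L]
          flip <- auc_rank(as.integer(as.factor(y) == pos),
                           pr[, pos]) < 0.5
        }
        list(svm = fit, flip = flip, positive = levels(as.factor(y))[2L])
      },
      score = function(obj, x) {
        pr <- attr(stats::predict(obj$svm, as.matrix(x),
                                  probability = TRUE), "probabilities")
        if (multi) pr[, sort(colnames(pr)), drop = FALSE]
        else if (obj$flip) 1 - pr[, obj$positive]
        else pr[, obj$positive]
      }),
    rf = list(
      fit = function(x, y, seed, ...) {
        set.seed(seed)
        randomForest::randomForest(as.data.frame(x), as.factor(y),
                                   ntree = 500)
      },
      score = function(obj, x) {
        pr <- stats::predict(obj, as.data.frame(x), type = "prob")
        if (multi) pr else pr[, 2L]
      }),
    xgb = list(
      fit = function(x, y, seed, ...) {
        y <- as.factor(y)
        if (multi) {
          set.seed(seed)
          dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                         label = as.integer(y) - 1L)
          params <- list(objective = "multi:softprob",
                         num_class = nlevels(y), max_depth = 6,
                         min_child_weight = 3, eta = 0.05, gamma = 0.1,
                         subsample = 0.8, nthread = 1)
          list(bst = xgboost::xgb.train(params, dtrain, nrounds = 200,
                                        verbose = 0),
               classes = levels(y))
        } else {
          y01 <- as.integer(y == levels(y)[2L])
          tp <- xgb_tuned_params(x, y01, tuner, cfg, seed)
          list(bst = fit_xgb(x, y01,
                             params = tp[setdiff(names(tp), "nrounds")],
                             nrounds = tp$nrounds, seed = seed),
               params = tp)
        }
      },
      score = function(obj, x) {
        p <- stats::predict(obj$bst, as.matrix(x))
        if (multi) {
          m <- if (is.matrix(p)) p
               else matrix(p, ncol = length(obj$classes), byrow = TRUE)
          colnames(m) <- obj$classes
          m
        } else p
      })
  )
  backends
}

#' Nested cross-validated model benchmark
#'
#' Runs every configured model over identical stratified outer folds (each
#' held-out fold is the 20% test split); training-fold-only preprocessing
#' (optional rebalancing for the binary task) guards against leakage, and the
#' inner tuner (if any) sees only training data. Out-of-fold predictions are
#' pooled into the test metric panel; train panels average the within-fold
#' training metrics. Models without an installed backend are skipped with a
#' log entry, never silently.
#'
#' @param x Feature data.frame (numeric columns).
#' @param y Labels: binary factor/0-1 for `task = "binary"`, three-class
#'   factor for `"multiclass"`.
#' @param config A [bench_config()].
#' @return Object of class `benchmark_result`: per-model `train`/`test`
#'   metric panels, `skipped` log, `config`, and `gap` (overfit report).
#' @export
run_benchmark <- function(x, y, config = bench_config()) {
  x <- as.data.frame(x)
  multi <- config$task == "multiclass"
  y <- as.factor(y)
  if (multi) stopifnot(nlevels(y) >= 3L) else stopifnot(nlevels(y) == 2L)
  backends <- model_backends(config$task, config$tuner, config)

  folds <- stratified_folds(y, config$outer_folds,
                            seed = derive_seed(config$seed, "outer"))
  skipped <- character(0)
  results <- list()
  for (mdl in config$models) {
    if (!mdl %in% names(backends)) {
      skipped <- c(skipped, sprintf(
        "%s: no installed backend in this stack; skipped", mdl))
      next
    }
    bk <- backends[[mdl]]
    oof_score <- NULL; oof_true <- NULL
    train_panels <- list()
    ok <- TRUE
    for (f in seq_len(config$outer_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
      if (!multi && config$rebalance_method != "none") {
        rb <- rebalance(xtr, ytr, method = config$rebalance_method,
                        seed = derive_seed(config$seed,
                                           paste0("rb", f)))
        xtr <- as.data.frame(rb$x); ytr <- rb$y
      }
      seed_f <- derive_seed(config$seed, paste0(mdl, "_fold", f))
      obj <- tryCatch(bk$fit(xtr, ytr, seed_f),
                      error = function(e) e)
      if (inherits(obj, "error")) {
        skipped <- c(skipped, sprintf("%s: fit failed (%s); skipped",
                                      mdl, conditionMessage(obj)))
        ok <- FALSE; break
      }
      s_tr <- bk$score(obj, xtr)
      s_te <- bk$score(obj, x[te, , drop = FALSE])
      if (multi) {
        pred_tr <- colnames(s_tr)[max.col(s_tr)]
        train_panels[[f]] <- metric_panel(ytr,
                                          factor(pred_tr, levels(y)), s_tr,
                                          averaging = "macro", n_boot = 0L)
        oof_score <- rbind(oof_score, s_te)
        oof_true <- c(oof_true, as.character(y[te]))
      } else {
        ytr01 <- as.integer(ytr == levels(ytr)[2L])
        train_panels[[f]] <- metric_panel(ytr01, as.integer(s_tr >= 0.5),
                                          s_tr, n_boot = 0L)
        oof_score <- c(oof_score, s_te)
        oof_true <- c(oof_true, as.character(y[te]))
      }
    }
    if (!ok) next
    avg_train <- function(field) mean(vapply(train_panels, function(p)
      as.numeric(p[[field]]), numeric(1)))
    train <- list(acc = avg_train("acc"), pre = avg_train("pre"),
                  tpr = avg_train("tpr"), tnr = avg_train("tnr"),
                  f1 = avg_train("f1"), auc = avg_train("auc"))
    if (multi) {
      yt <- factor(oof_true, levels(y))
      pred <- factor(colnames(oof_score)[max.col(oof_score)], levels(y))
      test <- metric_panel(yt, pred, oof_score, averaging = "macro",
                           n_boot = config$n_boot,
                           seed = derive_seed(config$seed, "boot"))
    } else {
      yt <- as.integer(factor(oof_true, levels(y)) == levels(y)[2L])
      test <- metric_panel(yt, as.integer(oof_score >= 0.5), oof_score,
                           n_boot = config$n_boot,
                           seed = derive_seed(config$seed, "boot"))
    }
    results[[mdl]] <- list(train = train, test = test)
  }
  gap <- if (length(results))
    overfit_gap(vapply(results, function(r) r$train$auc, numeric(1)),
                vapply(results, function(r) r$test$auc, numeric(1)))
  else NULL
  structure(list(models = results, skipped = skipped, gap = gap,
                 config = config, folds = folds),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark (", x$config$task, ", ", x$config$outer_folds,
      "-fold nested CV)\n", sep = "")
  for (nm in names(x$models)) {
    r <- x$models[[nm]]
    cat(sprintf("  %-14s train AUC %.3f | test ", nm, r$train$auc))
    print(r$test)
  }
  for (s in x$skipped) cat("  [skipped]", s, "\n")
  invisible(x)
}
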