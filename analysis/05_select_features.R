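#!/usr/bin/env Rscript
# Stage 5: rebalance the binary outcome with SMOTE-ENN, rank features by
# random-forest and boosted-tree importance (5% threshold), evaluate the
# D1/D2/union/intersection candidate sets, and summarize SHAP directions.

library(traumaprog)

res_dir <- "results/analysis"
seed <- 20260925L
cohort <- read_cohort(file.path(res_dir, "cohort_imputed.csv"))
selected <- readLines(file.path(res_dir, "screened_variables.txt"))

y <- dichotomize_outcome(cohort$outcome)
x <- cohort[selected]
x[] <- lapply(x, function(v)
  if (is.character(v) || is.factor(v)) as.integer(as.factor(v)) else v)

rb <- rebalance(x, y, method = "smote_enn",
                seed = derive_seed(seed, "rebalance"))
print(rb)

scr <- importance_screen(rb$x, rb$y, threshold = 0.05,
                         seed = derive_seed(seed, "importance"))
cat("\nRF retained:", scr$rf$retained, "\n")
cat("XGB retained:", scr$xgb$retained, "\n")

sets <- build_candidate_sets(scr$rf$retained, scr$xgb$retained)
print(sets$cardinalities)

ev <- evaluate_candidate_sets(sets, as.data.frame(rb$x), rb$y,
                              seed = derive_seed(seed, "evaluate"))
cat("\nper-set boosted-tree test AUC:\n")
for (nm in names(ev$sets))
  cat(sprintf("  %-15s |%2d features| CV AUC %.3f  test AUC %.3f\n", nm,
              length(ev$sets[[nm]]$features), ev$sets[[nm]]$cv_auc,
              ev$sets[[nm]]$test$auc))
cat("best set:", ev$best, "\n")

final_feats <- ev$sets[[ev$best]]$features
epv_check(length(final_feats), sum(y == "poor"))

shap <- shap_summary(ev$sets[[ev$best]]$model,
                     as.data.frame(rb$x)[ev$split$test, final_feats,
                                         drop = FALSE])
cat("\nSHAP summary (held-out fold):\n")
print(shap)

write.csv(shap, file.path(res_dir, "shap_summary.csv"), row.names = FALSE)
writeLines(final_feats, file.path(res_dir, "final_features.txt"))
jsonlite::write_json(
  list(rebalance = list(method = rb$method, before = rb$counts_before,
                        after = rb$counts_after),
       importances = list(rf = as.list(scr$rf$importance),
                          xgb = as.list(scr$xgb$importance)),
       sets = sets[c("D1", "D2", "D_union", "D_intersection")],
       best = ev$best,
       test_auc = lapply(ev$sets, function(s) s$test$auc)),
  file.path(res_dir, "screening_report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
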