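#!/usr/bin/env Rscript
# Stage 4: simulated-imputation selection for missing values, then
# univariate screening of every candidate variable across the three outcome
# groups, and the timeliness exclusion before modelling.

library(traumaprog)

res_dir <- "results/analysis"
seed <- 20260925L
cohort <- read_cohort(file.path(res_dir, "cohort_composite.csv"))

feats <- setdiff(names(cohort), c("patient_id", "outcome",
                                  "primary_dx_text", "other_dx_text"))
# categorical columns come back from CSV as character; restore factors
for (nm in feats) {
  if (is.character(cohort[[nm]])) cohort[[nm]] <- factor(cohort[[nm]])
}

audit <- impute_select(cohort[feats], seed = derive_seed(seed, "impute"))
cat("imputation change scores (smallest wins):\n")
print(round(audit$scores, 5))
cat("chosen:", audit$chosen, "\n\n")
cohort[feats] <- audit$imputed

report <- univariate_screen(cohort[feats], cohort$outcome, alpha = 0.05)
write.csv(report, file.path(res_dir, "univariate_report.csv"),
          row.names = FALSE)
cat(sprintf("univariate screen: %d of %d variables significant at 0.05\n",
            sum(report$significant), nrow(report)))

exclusions <- c("rescue_count", "surgery")  # not reliably known at admission
selected <- timeliness_filter(report, exclusions)
cat(sprintf("after timeliness exclusion of %s: %d variables retained\n",
            paste(exclusions, collapse = ", "), length(selected)))
writeLines(selected, file.path(res_dir, "screened_variables.txt"))
write_cohort(cohort, file.path(res_dir, "cohort_imputed.csv"))
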