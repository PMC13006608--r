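#!/usr/bin/env Rscript
# Stage 3: composite severity over the six AIS regions -- CRITIC objective
# weights vs equal weights vs ISS -- compared on discrimination,
# calibration and decision-curve net benefit against the binary outcome.

library(traumaprog)

res_dir <- "results/analysis"
cohort <- read_cohort(file.path(res_dir, "cohort_scored.csv"))

ais <- as.matrix(cohort[paste0("ais_", ais_regions())])
colnames(ais) <- ais_regions()
y <- as.integer(dichotomize_outcome(cohort$outcome) == "poor")

cmp <- compare_schemes(ais, y)
cat("CRITIC weight table:\n")
print(cmp$critic_table)
cat("\nscheme comparison:\n")
for (nm in c("critic", "equal", "iss")) {
  cat(sprintf("  %-7s AUC %.3f | H-L p %.3f\n", nm, cmp[[nm]]$auc,
              cmp[[nm]]$hl$p_value))
}

cohort$ais_weighted <- weighted_composite(ais, cmp$critic_table$weight)
cohort$iss <- iss_score(ais)
write_cohort(cohort, file.path(res_dir, "cohort_composite.csv"))
write.csv(cmp$critic_table, file.path(res_dir, "critic_table.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(auc = lapply(cmp[c("critic", "equal", "iss")], `[[`, "auc"),
       hl_p = lapply(cmp[c("critic", "equal", "iss")],
                     function(s) s$hl$p_value)),
  file.path(res_dir, "scheme_comparison.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
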