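#!/usr/bin/env Rscript
# Stage 2: score the free-text diagnoses against the keyword library and
# solve the module weights with the genetic algorithm (variance objective).

library(traumaprog)

res_dir <- "results/analysis"
seed <- 20260925L

cohort <- read_cohort(file.path(res_dir, "cohort.csv"))
scored <- score_cohort_text(cohort, optimize = TRUE,
                            config = ga_config(seed = derive_seed(seed,
                                                                  "score")))
cohort$primary_dx_score <- scored$scores$primary_dx_score
cohort$other_dx_score <- scored$scores$other_dx_score
write_cohort(cohort, file.path(res_dir, "cohort_scored.csv"))

for (cat_name in c("primary", "other")) {
  fit <- scored$fits[[cat_name]]
  cat(sprintf("%s diagnosis: objective (score variance) = %.3f\n",
              cat_name, fit$objective))
  print(fit$weights)
}
jsonlite::write_json(
  list(primary = list(weights = as.list(scored$fits$primary$weights),
                      objective = scored$fits$primary$objective),
       other = list(weights = as.list(scored$fits$other$weights),
                    objective = scored$fits$other$objective)),
  file.path(res_dir, "text_weights.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
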