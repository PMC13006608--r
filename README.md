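# traumaprog

Prognosis modelling for severe trauma admissions, end to end and fully
seeded: free-text diagnoses are scored against a modular keyword library
whose weights are solved by a genetic algorithm; regional Abbreviated
Injury Scale (AIS) grades are compressed into composite severity scores
(CRITIC objective weighting, equal weights, ISS); candidate predictors are
screened univariately, rebalanced with SMOTE-ENN and filtered by
tree-ensemble importance; and the final models are an interpretable
backward-stepwise logistic regression with a nomogram plus a nested
cross-validated benchmark of tabular classifiers. A synthetic-cohort
generator emulating a 292-patient three-class registry (108 cured, 130
improved, 54 poor prognosis) makes the whole pipeline testable without
patient data.

The package is aimed at biostatisticians and clinical data scientists who
want a reproducible reference implementation of this analysis style —
every stage is an exported, documented, tested function.

## The core quantities

**Diagnostic text score.** For patient *i*, module weights δ_j ∈ [0,5] and
keyword match counts N_ij,

    F_i = Σ_j δ_j · N_ij,

with δ solved by a genetic algorithm maximizing the population variance
σ² = (1/n) Σ_i (F_i − F̄)² of the score series. On the default integer
encoding the GA is verified against the exhaustive 6⁷-grid optimum.

**CRITIC composite.** Per AIS region: variability S_j (SD of the min–max
normalized column), conflict R_j = Σ_k (1 − r_jk), information
C_j = S_j·R_j, weight w_j = C_j / Σ C. Compared against equal weights and
ISS (sum of squares of the three worst regions, 75 if any region is 6) by
AUC, Hosmer–Lemeshow calibration and decision-curve net benefit.

**Stepwise logistic model.** Backward elimination by likelihood-ratio
p-value (α_exit = 0.10, AIC tie-break), reported as B, SE, Wald = (B/SE)²,
Exp(B) = e^B with 95% CI e^(B ± 1.96·SE), visualized as a 0–100-point
nomogram with bootstrap calibration and C-index.

## Worked example

```r
library(traumaprog)

co <- generate_cohort(cohort_spec(seed = 7))
table(co$outcome)
#>     cure improved     poor
#>      108      130       54
table(dichotomize_outcome(co$outcome))
#> good poor
#>  238   54        # imbalance ratio 238/54 ≈ 4.4:1

# score the diagnosis texts with GA-solved module weights
sc <- score_cohort_text(co, config = ga_config(seed = 1))
sc$fits$primary$objective          # score variance attained by the solver

# composite AIS schemes vs the binary outcome
ais <- as.matrix(co[paste0("ais_", ais_regions())])
cmp <- compare_schemes(ais, as.integer(dichotomize_outcome(co$outcome) == "poor"))
cmp$critic_table                   # variability, conflict, information, weight

# one call for the whole analysis
m <- run_pipeline(run_config(seed = 42))
m$status                           # "ok", 7 stage records with file hashes
```

Running the numbered drivers in `analysis/` (01 → 06) reproduces the full
narrative on the 292-patient synthetic cohort and writes all tables under
`results/analysis/`. On the shipped seed the pipeline prints, among other
things: a 4.4:1 binary imbalance optimized to 1.10 by SMOTE-ENN
(238:54 → 216:238), a best candidate feature set with held-out
boosted-tree AUC 0.989, a stepwise model whose nomogram reaches C-index
0.912 (95% CI 0.861–0.956) with bootstrap calibration MAE 0.035, and a
binary benchmark where gradient boosting attains test AUC 0.911
(95% CI 0.864–0.951) while the overfit-gap rule flags the RBF-SVM
(train − test AUC gap 0.320 > 0.15). Exact values depend only on the seed
at the top of each script.

## Layout

```
R/                  implementation (one file per analysis stage)
analysis/           numbered narrative drivers over the package
inst/extdata/       keyword library, distribution targets, reference tables
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R   headline-quantity recomputation
vignettes/          methods vignette (model, parameters, design choices)
```
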