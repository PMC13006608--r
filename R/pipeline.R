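#' Pipeline run configuration
#'
#' One configuration drives the whole analysis: cohort spec, text-scoring GA
#' settings, screening thresholds and the benchmark config, plus a single
#' global seed fanned out to per-stage seeds by [derive_seed()].
#'
#' @param seed Global integer seed.
#' @param output_dir Directory for stage artifacts.
#' @param cohort A [cohort_spec()] (its own seed is overridden by the
#'   derived stage seed).
#' @param ga A [ga_config()] for the weight solver.
#' @param alpha Univariate significance level.
#' @param exclusions Timeliness exclusions removed before modelling.
#' @param importance_threshold Importance share cut-off.
#' @param rebalance_method Rebalancing method for the binary screen.
#' @param bench A [bench_config()] template (task/seed set per stage).
#' @param stages Character vector of stages to run, in order.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, output_dir = tempfile("trauma_run_"),
                       cohort = cohort_spec(),
                       ga = ga_config(),
                       alpha = 0.05,
                       exclusions = c("rescue_count", "surgery"),
                       importance_threshold = 0.05,
                       rebalance_method = "smote_enn",
                       bench = bench_config(n_boot = 100L),
                       stages = c("simulate", "score_text", "composite",
                                  "preprocess", "screen", "select_features",
                                  "model")) {
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 cohort = cohort, ga = ga, alpha = alpha,
                 exclusions = exclusions,
                 importance_threshold = importance_threshold,
                 rebalance_method = rebalance_method, bench = bench,
                 stages = stages),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields only; nested specs use package defaults overridden by any
#' scalar fields present under `cohort`, `ga` and `bench`.
#'
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  yml <- yaml::read_yaml(path)
  co <- yml$cohort %||% list()
  cohort <- cohort_spec(n_cure = co$n_cure %||% 108L,
                        n_improved = co$n_improved %||% 130L,
                        n_poor = co$n_poor %||% 54L,
                        missing_rate = co$missing_rate %||% 0.03)
  ga_y <- yml$ga %||% list()
  ga <- ga_config(pop_size = ga_y$pop_size %||% 60L,
                  generations = ga_y$generations %||% 100L)
  be <- yml$bench %||% list()
  bench <- bench_config(models = be$models %||%
                          c("l1_logistic", "l2_logistic", "svm_rbf", "rf",
                            "xgb"),
                        tuner = be$tuner %||% "none",
                        n_boot = be$n_boot %||% 100L)
  run_config(seed = yml$seed %||% 1L,
             output_dir = yml$output_dir %||% tempfile("trauma_run_"),
             cohort = cohort, ga = ga,
             alpha = yml$alpha %||% 0.05,
             exclusions = unlist(yml$exclusions %||%
                                   c("rescue_count", "surgery")),
             importance_threshold = yml$importance_threshold %||% 0.05,
             rebalance_method = yml$rebalance_method %||% "smote_enn",
             bench = bench,
             stages = unlist(yml$stages %||%
                               c("simulate", "score_text", "composite",
                                 "preprocess", "screen", "select_features",
                                 "model")))
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(as.character(h), basename(paths))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in order (simulate, score_text, composite,
#' preprocess, screen, select_features, model), writing every stage's
#' numeric outputs as CSV/JSON under `config$output_dir` and recording a
#' manifest: per stage the derived seed, output files with md5 hashes and
#' elapsed wall-clock. A stage failure halts the run with a structured error
#' naming the stage; the manifest (with the failure recorded) is still
#' written.
#'
#' @param config A [run_config()].
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   written to `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL
  cfg_hash <- tools::md5sum(
    {tmp <- tempfile(); saveRDS(serialize_config(cfg_for_hash), tmp); tmp})
  manifest <- list(config_hash = unname(as.character(cfg_hash)),
                   seed = config$seed, stages = list(), status = "ok")

  state <- new.env(parent = emptyenv())

  stage_defs <- list(
    simulate = function(seed) {
      spec <- config$cohort
      spec$seed <- seed
      state$cohort <- generate_cohort(spec)
      write_cohort(state$cohort, out("cohort.csv"))
      c(out("cohort.csv"), out("cohort.csv.json"))
    },
    score_text = function(seed) {
      cfg <- config$ga
      cfg$seed <- seed
      sc <- score_cohort_text(state$cohort, config$cohort$library,
                              optimize = TRUE, config = cfg)
      state$cohort$primary_dx_score <- sc$scores$primary_dx_score
      state$cohort$other_dx_score <- sc$scores$other_dx_score
      state$text_fits <- sc$fits
      write_json_file(list(
        primary = list(weights = as.list(sc$fits$primary$weights),
                       objective = sc$fits$primary$objective),
        other = list(weights = as.list(sc$fits$other$weights),
                     objective = sc$fits$other$objective)),
        out("text_weights.json"))
      out("text_weights.json")
    },
    composite = function(seed) {
      ais <- as.matrix(state$cohort[paste0("ais_", ais_regions())])
      colnames(ais) <- ais_regions()
      y <- dichotomize_outcome(state$cohort$outcome)
      cmp <- compare_schemes(ais, as.integer(y == "poor"))
      state$cohort$ais_weighted <-
        weighted_composite(ais, cmp$critic_table$weight)
      state$cohort$iss <- iss_score(ais)
      state$scheme_comparison <- cmp
      utils::write.csv(cmp$critic_table, out("critic_table.csv"),
                       row.names = FALSE)
      write_json_file(list(
        auc = lapply(cmp[c("critic", "equal", "iss")], `[[`, "auc"),
        hl_p = lapply(cmp[c("critic", "equal", "iss")],
                      function(s) s$hl$p_value)),
        out("scheme_comparison.json"))
      c(out("critic_table.csv"), out("scheme_comparison.json"))
    },
    preprocess = function(seed) {
      feats <- setdiff(names(state$cohort),
                       c("patient_id", "outcome", "primary_dx_text",
                         "other_dx_text"))
      audit <- impute_select(state$cohort[feats], seed = seed)
      state$cohort[feats] <- audit$imputed
      state$imputation <- audit
      write_json_file(list(chosen = audit$chosen,
                           scores = as.list(audit$scores),
                           definition = audit$change_score_definition),
                      out("imputation_audit.json"))
      out("imputation_audit.json")
    },
    screen = function(seed) {
      feats <- setdiff(names(state$cohort),
                       c("patient_id", "outcome", "primary_dx_text",
                         "other_dx_text"))
      rep_ <- univariate_screen(state$cohort[feats], state$cohort$outcome,
                                alpha = config$alpha)
      state$univariate <- rep_
      state$screened <- timeliness_filter(rep_, config$exclusions)
      utils::write.csv(rep_, out("univariate_report.csv"),
                       row.names = FALSE)
      out("univariate_report.csv")
    },
    select_features = function(seed) {
      y <- dichotomize_outcome(state$cohort$outcome)
      xall <- encode_numeric(state$cohort[state$screened])
      rb <- rebalance(xall, y, method = config$rebalance_method,
                      seed = derive_seed(seed, "rebalance"))
      scr <- importance_screen(rb$x, rb$y,
                               threshold = config$importance_threshold,
                               seed = derive_seed(seed, "importance"))
      sets <- build_candidate_sets(scr$rf$retained, scr$xgb$retained)
      ev <- evaluate_candidate_sets(sets, as.data.frame(rb$x), rb$y,
                                    seed = derive_seed(seed, "evaluate"),
                                    n_boot = 100L)
      shap <- shap_summary(ev$sets[[ev$best]]$model,
                           as.data.frame(rb$x)[ev$split$test,
                                               ev$sets[[ev$best]]$features,
                                               drop = FALSE])
      epv_check(length(ev$sets[[ev$best]]$features), sum(y == "poor"))
      state$selection <- list(rebalance = rb, screen = scr, sets = sets,
                              evaluation = ev, shap = shap)
      state$final_features <- ev$sets[[ev$best]]$features
      write_json_file(list(
        rebalance = list(method = rb$method,
                         before = rb$counts_before,
                         after = rb$counts_after),
        importances = list(rf = as.list(scr$rf$importance),
                           xgb = as.list(scr$xgb$importance)),
        sets = sets[c("D1", "D2", "D_union", "D_intersection")],
        best = ev$best,
        test_auc = lapply(ev$sets, function(s) s$test$auc)),
        out("screening_report.json"))
      utils::write.csv(state$selection$shap, out("shap_summary.csv"),
                       row.names = FALSE)
      c(out("screening_report.json"), out("shap_summary.csv"))
    },
    model = function(seed) {
      y <- dichotomize_outcome(state$cohort$outcome)
      xmod <- encode_numeric(state$cohort[state$final_features])
      fit <- stepwise_logistic(as.data.frame(xmod),
                               as.integer(y == "poor"))
      nomo <- if (length(fit$retained))
        build_nomogram(fit, as.data.frame(xmod),
                       as.integer(y == "poor"), n_boot = 200L,
                       seed = derive_seed(seed, "nomogram"))
      else NULL
      bcfg <- config$bench
      bcfg$seed <- derive_seed(seed, "bench_binary")
      bcfg$task <- "binary"
      bcfg$rebalance_method <- config$rebalance_method
      bench_bin <- run_benchmark(as.data.frame(xmod), y, bcfg)
      mcfg <- config$bench
      mcfg$task <- "multiclass"
      mcfg$seed <- derive_seed(seed, "bench_multi")
      mcfg$models <- intersect(mcfg$models, c("rf", "xgb", "l1_logistic",
                                              "l2_logistic", "svm_rbf"))
      bench_multi <- run_benchmark(as.data.frame(xmod),
                                   state$cohort$outcome, mcfg)
      state$models <- list(stepwise = fit, nomogram = nomo,
                           binary = bench_bin, multiclass = bench_multi)
      utils::write.csv(fit$table, out("stepwise_table.csv"),
                       row.names = FALSE)
      panel_json <- function(b) lapply(b$models, function(r) list(
        train = r$train[c("acc", "pre", "tpr", "tnr", "f1", "auc")],
        test = r$test[c("acc", "pre", "tpr", "tnr", "f1", "auc")]))
      write_json_file(list(binary = panel_json(bench_bin),
                           multiclass = panel_json(bench_multi),
                           skipped = c(bench_bin$skipped,
                                       bench_multi$skipped),
                           gap = bench_bin$gap),
                      out("benchmark_report.json"))
      if (!is.null(nomo))
        write_json_file(list(
          c_index = nomo$c_index, c_index_ci = nomo$c_index_ci,
          calibration_mae = nomo$calibration_mae,
          points = lapply(nomo$points, function(p)
            p[c("variable", "coefficient", "range", "max_points")])),
          out("nomogram.json"))
      c(out("stepwise_table.csv"), out("benchmark_report.json"),
        if (!is.null(nomo)) out("nomogram.json"))
    })

  for (st in config$stages) {
    if (!st %in% names(stage_defs))
      stop("unknown stage: ", st)
    seed_st <- derive_seed(config$seed, st)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(stage_defs[[st]](seed_st), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      manifest$status <- "failed"
      manifest$stages[[st]] <- list(stage = st, seed = seed_st,
                                    status = "error",
                                    message = conditionMessage(res),
                                    elapsed = elapsed)
      write_json_file(manifest, out("manifest.json"))
      stop("pipeline stage '", st, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[st]] <- list(stage = st, seed = seed_st,
                                  status = "ok",
                                  outputs = as.list(hash_files(res)),
                                  elapsed = elapsed)
    message(sprintf("[%s] seed=%d elapsed=%.1fs", st, seed_st, elapsed))
  }
  write_json_file(manifest, out("manifest.json"))
  state$manifest <- manifest
  structure(manifest, class = "run_manifest", state = as.list(state))
}

# one-hot-free numeric encoding: factors become integer level codes
# (ordered by level), keeping the tabular learners backend-agnostic
encode_numeric <- function(df) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.factor(df[[nm]]) || is.character(df[[nm]]))
      df[[nm]] <- as.integer(as.factor(df[[nm]]))
  }
  as.matrix(df)
}

serialize_config <- function(cfg) {
  # drop closures/environments so the hash depends only on parameter values
  scrub <- function(x) {
    if (is.function(x) || is.environment(x)) return(NULL)
    if (is.list(x)) return(lapply(x, scrub))
    x
  }
  scrub(unclass(cfg))
}

#' Deterministic fingerprint of a run manifest
#'
#' Hash over the config hash and every stage's output-file hashes (elapsed
#' times excluded), so two runs of the same configuration and seed compare
#' equal exactly when their artifacts are byte-identical.
#'
#' @param manifest A `run_manifest`.
#' @return A character md5 fingerprint.
#' @export
manifest_fingerprint <- function(manifest) {
  core <- list(config = manifest$config_hash, seed = manifest$seed,
               stages = lapply(manifest$stages, function(s)
                 s[c("stage", "seed", "status", "outputs")]))
  tmp <- tempfile()
  writeLines(jsonlite::toJSON(core, auto_unbox = TRUE), tmp)
  unname(as.character(tools::md5sum(tmp)))
}
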