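#' Default per-class distribution targets for the synthetic cohort
#'
#' Long-format table: one row per feature x outcome class. Continuous
#' features carry median / P25 / P75 targets (the cohorts they emulate are
#' right-skewed, so features are drawn log-normal); count features carry a
#' Poisson rate; categorical features carry level labels and per-class level
#' counts.
#'
#' @param path Optional alternative CSV.
#' @return A data.frame of feature specifications.
#' @export
feature_targets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "feature_targets.csv",
                        package = "traumaprog", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cohort specification
#'
#' @param n_cure,n_improved,n_poor Per-class sample sizes; the default is the
#'   292-patient study shape 108/130/54.
#' @param missing_rate MCAR missingness fraction per eligible column, must be
#'   `< 0.05`.
#' @param seed Integer seed; fully determines the generated cohort.
#' @param targets Feature-target table (see [feature_targets()]).
#' @param library Keyword library used to assemble diagnosis texts.
#' @param text_risk_odds Multiplicative odds applied to high-weight modules
#'   for poor-prognosis records when sampling text content.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cure = 108L, n_improved = 130L, n_poor = 54L,
                        missing_rate = 0.03, seed = 1L,
                        targets = feature_targets(),
                        library = default_keyword_library(),
                        text_risk_odds = 2.5) {
  n <- c(n_cure, n_improved, n_poor)
  if (any(n < 0L)) stop("class counts must be non-negative")
  if (sum(n) < 30L) stop("total cohort size must be at least 30")
  if (missing_rate < 0 || missing_rate >= 0.05)
    stop("missing_rate must be in [0, 0.05)")
  structure(list(n_cure = as.integer(n_cure),
                 n_improved = as.integer(n_improved),
                 n_poor = as.integer(n_poor),
                 missing_rate = missing_rate, seed = as.integer(seed),
                 targets = targets, library = library,
                 text_risk_odds = text_risk_odds),
            class = "cohort_spec")
}

#' Read a cohort specification from YAML
#'
#' Only scalar fields are read from the file; targets and library use the
#' package defaults unless paths are given under `targets_csv` /
#' `library_json`.
#'
#' @param path YAML file path.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_spec(
    n_cure = y$n_cure %||% 108L, n_improved = y$n_improved %||% 130L,
    n_poor = y$n_poor %||% 54L, missing_rate = y$missing_rate %||% 0.03,
    seed = y$seed %||% 1L,
    targets = if (!is.null(y$targets_csv)) feature_targets(y$targets_csv)
              else feature_targets(),
    library = if (!is.null(y$library_json)) read_keyword_library(y$library_json)
              else default_keyword_library(),
    text_risk_odds = y$text_risk_odds %||% 2.5)
}

# log-normal parameters hitting a (median, IQR) target:
# median = exp(mu); IQR = 2*exp(mu)*sinh(z75*sigma) with z75 = qnorm(0.75)
lognormal_params <- function(median, p25, p75) {
  stopifnot(median > 0, p75 > p25)
  mu <- log(median)
  sigma <- asinh((p75 - p25) / (2 * median)) / stats::qnorm(0.75)
  c(mu = mu, sigma = sigma)
}

# per-class AIS severity profiles over codes 0..6, chosen once to put the
# cohort's ISS medians near the 20 / 22 / 29 gradient the generator emulates
ais_severity_probs <- function(outcome) {
  switch(outcome,
    cure     = c(0.235, 0.215, 0.305, 0.200, 0.040, 0.005, 0.000),
    improved = c(0.220, 0.200, 0.300, 0.230, 0.045, 0.005, 0.000),
    poor     = c(0.170, 0.160, 0.270, 0.270, 0.100, 0.028, 0.002))
}

# neutral filler vocabulary for diagnosis texts; deliberately free of
# anatomical terms so no filler can collide with a library keyword
filler_tokens <- function() {
  c("patient", "admitted", "with", "status", "noted", "on", "arrival",
    "stable", "under", "observation", "review", "planned", "management",
    "ongoing", "assessment")
}

sample_dx_text <- function(modules_keywords, weights, is_poor, risk_odds,
                           n_modules_range = c(1L, 3L)) {
  J <- length(modules_keywords)
  base <- rep(0.35, J)
  odds <- base / (1 - base)
  if (is_poor) odds[weights >= 4] <- odds[weights >= 4] * risk_odds
  p_inc <- odds / (1 + odds)
  inc <- stats::runif(J) < p_inc
  if (!any(inc)) inc[sample.int(J, 1L)] <- TRUE
  phrases <- character(0)
  for (j in which(inc)) {
    kws <- modules_keywords[[j]]
    n_k <- sample.int(min(2L, length(kws)), 1L)
    phrases <- c(phrases, sample(kws, n_k))
  }
  fill <- sample(filler_tokens(), sample(2:4, 1L), replace = TRUE)
  paste(sample(c(phrases, fill)), collapse = "; ")
}

#' Generate a synthetic trauma cohort
#'
#' Draws a seeded cohort with exact class counts, per-class log-normal
#' continuous features hitting median/IQR targets, Poisson count features,
#' categorical features from per-class level frequencies, six regional AIS
#' columns with class-dependent severity, and free-text diagnoses assembled
#' from the keyword library (poor-prognosis records sample high-weight
#' modules more often) plus neutral filler tokens. Missing cells are inserted
#' completely at random at `missing_rate` per eligible (lab/vital) column.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame: `patient_id`, `outcome`
#'   (factor cure/improved/poor), `primary_dx_text`, `other_dx_text`, six
#'   `ais_*` columns and the feature columns.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  counts <- c(cure = spec$n_cure, improved = spec$n_improved,
              poor = spec$n_poor)
  outcome <- factor(rep(names(counts), counts),
                    levels = c("cure", "improved", "poor"))
  n <- length(outcome)

  df <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                   outcome = outcome, stringsAsFactors = FALSE)

  # diagnosis texts
  for (cat_name in c("primary", "other")) {
    mods <- spec$library[[cat_name]]
    kw <- lapply(mods, `[[`, "keywords")
    w <- vapply(mods, `[[`, numeric(1), "weight")
    df[[paste0(cat_name, "_dx_text")]] <- vapply(seq_len(n), function(i) {
      sample_dx_text(kw, w, outcome[i] == "poor", spec$text_risk_odds)
    }, character(1))
  }

  # regional AIS
  for (r in ais_regions()) {
    v <- integer(n)
    for (cls in levels(outcome)) {
      idx <- which(outcome == cls)
      v[idx] <- sample(0:6, length(idx), replace = TRUE,
                       prob = ais_severity_probs(cls))
    }
    df[[paste0("ais_", r)]] <- v
  }

  # tabular features from targets
  tg <- spec$targets
  for (nm in unique(tg$name)) {
    rows <- tg[tg$name == nm, ]
    kind <- rows$kind[1L]
    v <- rep(NA_real_, n)
    if (kind == "categorical") v <- character(n)
    for (cls in levels(outcome)) {
      idx <- which(outcome == cls)
      row <- rows[rows$outcome == cls, ]
      if (nrow(row) != 1L) stop("targets missing class '", cls, "' for ", nm)
      if (kind == "continuous") {
        pars <- lognormal_params(row$median, row$p25, row$p75)
        v[idx] <- stats::rlnorm(length(idx), pars["mu"], pars["sigma"])
      } else if (kind == "count") {
        v[idx] <- stats::rpois(length(idx), row$lambda)
      } else if (kind == "categorical") {
        levs <- strsplit(row$levels, "|", fixed = TRUE)[[1L]]
        cnt <- as.numeric(strsplit(row$counts, "|", fixed = TRUE)[[1L]])
        v[idx] <- sample(levs, length(idx), replace = TRUE,
                         prob = cnt / sum(cnt))
      } else stop("unknown feature kind: ", kind)
    }
    if (kind == "categorical") {
      levs <- strsplit(rows$levels[1L], "|", fixed = TRUE)[[1L]]
      v <- factor(v, levels = levs)
    }
    df[[nm]] <- v
  }

  # MCAR missingness on eligible (tabular feature) columns only; the
  # per-column count is capped so every realized proportion stays < 5%
  if (spec$missing_rate > 0) {
    cap <- ceiling(0.05 * n) - 1L
    for (nm in unique(tg$name)) {
      k <- min(stats::rbinom(1L, n, spec$missing_rate), cap)
      if (k > 0L) df[[nm]][sample.int(n, k)] <- NA
    }
  }
  attr(df, "spec") <- spec
  df
}

#' Collapse the three-class outcome to the binary prognosis label
#'
#' Cure and improved merge into the good-prognosis (negative) class; poor
#' prognosis is the positive class.
#'
#' @param outcome Factor/character vector with values cure / improved / poor.
#' @return Factor with levels `good`, `poor` (`poor` = positive class).
#' @export
dichotomize_outcome <- function(outcome) {
  outcome <- as.character(outcome)
  bad <- setdiff(unique(outcome), c("cure", "improved", "poor"))
  if (length(bad)) stop("unknown outcome label(s): ", paste(bad, collapse = ", "))
  factor(ifelse(outcome == "poor", "poor", "good"), levels = c("good", "poor"))
}

#' Write a cohort to CSV with a JSON sidecar
#'
#' The CSV has one row per patient, UTF-8, header row, missing values as
#' empty cells; the sidecar records the generating spec's scalar fields.
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @return Invisibly, the CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    side <- spec[c("n_cure", "n_improved", "n_poor", "missing_rate", "seed",
                   "text_risk_odds")]
    write_json_file(side, paste0(path, ".json"))
  }
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#' @param path CSV path.
#' @return Cohort data.frame with `outcome` releveled cure/improved/poor.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  if ("outcome" %in% names(df))
    df$outcome <- factor(df$outcome, levels = c("cure", "improved", "poor"))
  df
}
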