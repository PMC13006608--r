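impute_with <- function(df, fun) {
  for (nm in names(df)) {
    x <- df[[nm]]
    if (!anyNA(x)) next
    if (all(is.na(x))) stop("column '", nm, "' is entirely missing")
    fill <- fun(x)
    x[is.na(x)] <- fill
    df[[nm]] <- x
  }
  df
}

impute_mean_ <- function(df) {
  impute_with(df, function(x) {
    if (is.numeric(x)) mean(x, na.rm = TRUE) else stat_mode(x)
  })
}
impute_median_ <- function(df) {
  impute_with(df, function(x) {
    if (is.numeric(x)) stats::median(x, na.rm = TRUE) else stat_mode(x)
  })
}
impute_mode_ <- function(df) impute_with(df, stat_mode)

# compact chained-equations imputer: m independent chains, each initialized
# with mean/mode fills and refined by regressing each incomplete numeric
# column on the complete-data design (linear model + residual noise);
# incomplete categorical cells are drawn from observed level frequencies.
# Chains aggregate by mean (numeric) / mode (categorical).
impute_multiple_ <- function(df, m = 5L, iterations = 3L, seed = 1L) {
  set.seed(seed)
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  chains <- lapply(seq_len(m), function(chain) {
    imp <- impute_mean_(df)
    for (it in seq_len(iterations)) {
      for (nm in names(df)) {
        miss <- is.na(df[[nm]])
        if (!any(miss)) next
        if (is.numeric(df[[nm]])) {
          others <- setdiff(num_cols, nm)
          if (length(others)) {
            X <- as.matrix(imp[others])
            fit <- stats::lm.fit(cbind(1, X), imp[[nm]])
            beta <- fit$coefficients
            beta[is.na(beta)] <- 0     # aliased (collinear) columns drop out
            pred <- cbind(1, X) %*% beta
            sd_r <- stats::sd(fit$residuals)
            if (!is.finite(sd_r)) sd_r <- 0
            imp[[nm]][miss] <- pred[miss] +
              stats::rnorm(sum(miss), 0, sd_r)
          }
        } else {
          obs <- df[[nm]][!miss]
          imp[[nm]][miss] <- sample(obs, sum(miss), replace = TRUE)
        }
      }
    }
    imp
  })
  out <- df
  for (nm in names(df)) {
    miss <- is.na(df[[nm]])
    if (!any(miss)) next
    vals <- sapply(chains, function(ch) as.character(ch[[nm]][miss]))
    vals <- matrix(vals, nrow = sum(miss))
    if (is.numeric(df[[nm]])) {
      out[[nm]][miss] <- rowMeans(matrix(as.numeric(vals),
                                         nrow = sum(miss)))
    } else {
      out[[nm]][miss] <- apply(vals, 1L, stat_mode)
    }
  }
  out
}

# "degree of change" of an imputed table against the complete cases:
# numeric columns contribute |shift in mean|/sd_cc + |shift in variance|/var_cc,
# categorical columns the total-variation distance of level frequencies;
# averaged over the columns that had missing cells.
imputation_change_score <- function(imputed, original) {
  affected <- names(original)[vapply(original, anyNA, logical(1))]
  if (!length(affected)) return(0)
  shifts <- vapply(affected, function(nm) {
    cc <- original[[nm]][!is.na(original[[nm]])]
    full <- imputed[[nm]]
    if (is.numeric(cc)) {
      sd_cc <- stats::sd(cc)
      var_cc <- stats::var(cc)
      if (!is.finite(sd_cc) || sd_cc == 0) return(0)
      abs(mean(full) - mean(cc)) / sd_cc +
        abs(stats::var(full) - var_cc) / var_cc
    } else {
      levs <- unique(c(as.character(cc), as.character(full)))
      p <- table(factor(as.character(cc), levs)) / length(cc)
      q <- table(factor(as.character(full), levs)) / length(full)
      sum(abs(p - q)) / 2
    }
  }, numeric(1))
  mean(shifts)
}

#' Simulated-imputation selection
#'
#' Runs four candidate imputations (mean, mode, median, multiple) and scores
#' each by how much it perturbs the column distributions relative to the
#' complete cases; the candidate with the smallest change score is selected.
#' The change score is the mean, over columns with missing cells, of the
#' standardized absolute shifts in mean and variance (numeric columns) or the
#' total-variation distance of level frequencies (categorical columns). Ties
#' resolve in the fixed order mode, mean, median, multiple.
#'
#' @param df Data frame with missing cells (each column < 5% missing).
#' @param m,iterations Chained-equations settings for the multiple-imputation
#'   candidate.
#' @param seed Seed for the stochastic multiple-imputation candidate.
#' @return List of class `imputation_audit`: `chosen` (method name),
#'   `scores` (named numeric), `imputed` (table from the chosen method),
#'   `change_score_definition`.
#' @export
impute_select <- function(df, m = 5L, iterations = 3L, seed = 1L) {
  miss_frac <- vapply(df, function(x) mean(is.na(x)), numeric(1))
  if (any(miss_frac >= 0.05))
    warning("column(s) with >= 5% missing: ",
            paste(names(df)[miss_frac >= 0.05], collapse = ", "))
  candidates <- list(
    mode = function() impute_mode_(df),
    mean = function() impute_mean_(df),
    median = function() impute_median_(df),
    multiple = function() impute_multiple_(df, m, iterations, seed))
  tables <- lapply(candidates, function(f) f())
  scores <- vapply(tables, imputation_change_score, numeric(1),
                   original = df)
  chosen <- names(scores)[which.min(scores)]  # which.min: first = tie order
  structure(list(
    chosen = chosen, scores = scores, imputed = tables[[chosen]],
    change_score_definition = paste(
      "mean over columns with missing cells of",
      "|mean shift|/sd_cc + |variance shift|/var_cc (numeric) or",
      "total-variation distance of level frequencies (categorical),",
      "relative to complete cases")),
    class = "imputation_audit")
}

#' @export
print.imputation_audit <- function(x, ...) {
  cat("simulated-imputation audit\n")
  print(round(x$scores, 6))
  cat("chosen:", x$chosen, "\n")
  invisible(x)
}

#' Univariate screening across the three outcome groups
#'
#' Continuous features pass a per-group Shapiro-Wilk normality gate at
#' `alpha`: one-way ANOVA when every group looks normal, Kruskal-Wallis (with
#' the standard tie correction) otherwise. Categorical features use the
#' chi-square test on the contingency table. Zero-variance features are
#' flagged and not tested. No multiple-testing correction is applied at this
#' stage.
#'
#' @param df Data frame of features (no outcome column).
#' @param outcome Three-class factor.
#' @param alpha Significance level for both the normality gate and the
#'   significance flag.
#' @return Data frame of class `univariate_report`: `feature`, `test`,
#'   `statistic`, `p_value`, `significant`, `summary_cure`,
#'   `summary_improved`, `summary_poor`.
#' @export
univariate_screen <- function(df, outcome, alpha = 0.05) {
  outcome <- droplevels(as.factor(outcome))
  if (nlevels(outcome) < 2L) stop("need at least two outcome groups")
  if (any(table(outcome) == 0L)) stop("empty outcome group")

  summarize_group <- function(x, is_num) {
    if (is_num) {
      q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE)
      sprintf("%.1f (%.1f, %.1f)", q[1], q[2], q[3])
    } else {
      paste(table(x), collapse = ":")
    }
  }

  rows <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    keep <- !is.na(x)
    xx <- x[keep]; gg <- droplevels(outcome[keep])
    is_num <- is.numeric(xx) && length(unique(xx)) > 2L
    summaries <- vapply(levels(outcome), function(lv)
      summarize_group(x[keep & outcome == lv], is_num), character(1))
    if (length(unique(xx)) < 2L) {
      return(data.frame(feature = nm, test = "none", statistic = NA_real_,
                        p_value = NA_real_, significant = FALSE,
                        flagged = TRUE,
                        t(summaries), stringsAsFactors = FALSE))
    }
    if (is_num) {
      normal <- all(vapply(levels(gg), function(lv) {
        v <- xx[gg == lv]
        if (length(v) < 3L || length(v) > 5000L) return(FALSE)
        if (stats::sd(v) == 0) return(FALSE)
        stats::shapiro.test(v)$p.value >= alpha
      }, logical(1)))
      if (normal) {
        fit <- stats::aov(xx ~ gg)
        s <- summary(fit)[[1L]]
        stat <- s[["F value"]][1L]
        p <- s[["Pr(>F)"]][1L]
        test <- "anova"
      } else {
        kw <- stats::kruskal.test(xx, gg)
        stat <- unname(kw$statistic)
        p <- kw$p.value
        test <- "kruskal_wallis"
      }
    } else {
      tab <- table(xx, gg)
      cs <- suppressWarnings(stats::chisq.test(tab))
      stat <- unname(cs$statistic)
      p <- cs$p.value
      test <- "chi_square"
    }
    data.frame(feature = nm, test = test, statistic = stat, p_value = p,
               significant = is.finite(p) && p < alpha, flagged = FALSE,
               t(summaries), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("feature", "test", "statistic", "p_value", "significant",
                  "flagged", paste0("summary_", levels(outcome)))
  rownames(out) <- NULL
  class(out) <- c("univariate_report", "data.frame")
  out
}

#' Remove timeliness-limited features from the significant set
#'
#' Features that cannot reliably be collected at admission (e.g. rescue
#' counts, whether surgery was performed) are excluded from the screened set
#' before model construction; order is preserved.
#'
#' @param report A `univariate_report` (or data.frame with `feature` and
#'   `significant`).
#' @param exclusions Character vector of feature names to drop.
#' @return Character vector of retained significant feature names.
#' @export
timeliness_filter <- function(report, exclusions = character(0)) {
  sig <- report$feature[report$significant]
  sig[!sig %in% exclusions]
}
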