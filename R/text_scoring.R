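#' Normalize free-text for keyword matching
#'
#' Lowercases, maps punctuation to spaces and squeezes whitespace. Matching
#' downstream is plain codepoint substring search, so non-space-delimited
#' scripts work unchanged.
#'
#' @param text Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(text) {
  text[is.na(text)] <- ""
  out <- tolower(text)
  out <- gsub("[[:punct:]]+", " ", out)
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

count_occurrences <- function(text, keyword) {
  if (!nzchar(keyword) || !nzchar(text)) return(0L)
  m <- gregexpr(keyword, text, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' Count keyword matches per module
#'
#' For each module of one library category, counts the total occurrences of
#' its keywords in the normalized text. Every occurrence counts (a keyword
#' appearing three times contributes 3); distinct keywords are counted
#' independently, so overlapping matches of different keywords each count.
#'
#' @param text Character vector of free-text diagnoses (one per patient).
#' @param library A `keyword_library`.
#' @param category Which category's modules to match against.
#' @return An integer matrix, patients x modules, with module-name columns.
#' @export
count_matches <- function(text, library, category = "primary") {
  validate_keyword_library(library)
  category <- match.arg(category, names(library))
  mods <- library[[category]]
  norm <- normalize_text(text)
  counts <- vapply(mods, function(m) {
    kws <- normalize_text(m$keywords)
    vapply(norm, function(tx) {
      sum(vapply(kws, function(kw) count_occurrences(tx, kw), integer(1)))
    }, integer(1), USE.NAMES = FALSE)
  }, integer(length(norm)))
  counts <- matrix(as.integer(counts), nrow = length(norm),
                   dimnames = list(NULL, vapply(mods, `[[`, character(1),
                                                "module")))
  counts
}

#' Diagnostic text score
#'
#' The per-patient score is the weighted sum of module match counts,
#' `F_i = sum_j delta_j * N_ij`.
#'
#' @param counts Integer matrix (or single row) of match counts, columns =
#'   modules.
#' @param weights Numeric module weights, same length/order as the columns.
#' @return Numeric vector of scores, one per row of `counts`.
#' @export
diagnostic_score <- function(counts, weights) {
  counts <- rbind(counts)
  if (ncol(counts) != length(weights))
    stop("counts and weights disagree on module count")
  as.numeric(counts %*% as.numeric(weights))
}

#' Population-variance objective of a score series
#'
#' The weight solver maximizes the dispersion of the diagnostic scores,
#' measured as the population variance (divisor `n`):
#' `sigma^2 = (1/n) * sum_i (F_i - mean(F))^2`.
#'
#' @param scores Numeric vector of per-patient scores.
#' @return The population variance (>= 0).
#' @export
variance_objective <- function(scores) {
  if (!length(scores)) stop("empty score series")
  mean((scores - mean(scores))^2)
}

#' GA configuration for the weight solver
#'
#' @param pop_size,generations,crossover_rate,mutation_rate,elitism,tournament_size
#'   GA hyperparameters; defaults are the package's standing choices.
#' @param encoding `"integer"` searches weights on the grid `{0,...,5}`;
#'   `"continuous"` searches the box `[0, 5]^J`.
#' @param seed Integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 60L, generations = 100L,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      elitism = 2L, tournament_size = 3L,
                      encoding = c("integer", "continuous"), seed = 1L) {
  structure(list(pop_size = pop_size, generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, elitism = elitism,
                 tournament_size = tournament_size,
                 encoding = match.arg(encoding), seed = as.integer(seed)),
            class = "ga_config")
}

#' Exhaustive grid search for module weights
#'
#' Enumerates every integer weight vector on `{levels}^J` and returns the one
#' maximizing the population variance of the scores. Feasible for `J <= 7`
#' (6^7 = 279,936 candidates). Ties resolve to the lexicographically smallest
#' vector. Serves as the independent optimum against which the GA is checked.
#'
#' @param counts Match-count matrix (patients x modules).
#' @param levels Candidate per-module weights, default `0:5`.
#' @return List with `weights` (named) and `objective`.
#' @export
exhaustive_weight_search <- function(counts, levels = 0:5) {
  J <- ncol(counts)
  if (J > 7L) stop("exhaustive search is limited to J <= 7 modules")
  grid <- as.matrix(expand.grid(rep(list(levels), J), KEEP.OUT.ATTRS = FALSE))
  S <- counts %*% t(grid)                       # patients x candidates
  v <- colMeans(S^2) - colMeans(S)^2            # population variance
  best <- max(v)
  tied <- which(v >= best - 1e-9 * max(1, best))
  tied_rows <- grid[tied, , drop = FALSE]
  ord <- do.call(order, as.data.frame(tied_rows))
  w <- tied_rows[ord[1L], ]
  list(weights = stats::setNames(as.numeric(w), colnames(counts)),
       objective = v[tied[ord[1L]]])
}

#' Solve module weights by genetic algorithm
#'
#' Maximizes the population variance of the diagnostic scores over module
#' weights constrained to `[0, 5]` (integer grid by default). An all-constant
#' count matrix makes the objective flat in the weights; the result is then
#' flagged `degenerate` with zero weights.
#'
#' @param counts Match-count matrix (patients x modules), >= 2 rows.
#' @param config A [ga_config()].
#' @return List of class `weight_fit`: `weights` (named), `objective`,
#'   `degenerate`, `convergence` (best objective per generation), `config`.
#' @export
optimize_weights <- function(counts, config = ga_config()) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("need at least 2 patients")
  J <- ncol(counts)
  col_var <- apply(counts, 2L, stats::var)
  if (all(col_var == 0)) {
    return(structure(list(
      weights = stats::setNames(rep(0, J), colnames(counts)),
      objective = 0, degenerate = TRUE, convergence = numeric(0),
      config = config), class = "weight_fit"))
  }
  fitness <- function(w) variance_objective(as.numeric(counts %*% w))
  res <- ga_optimize(
    fitness, lower = rep(0, J), upper = rep(5, J),
    integer = config$encoding == "integer",
    pop_size = config$pop_size, generations = config$generations,
    crossover_rate = config$crossover_rate,
    mutation_rate = config$mutation_rate, elitism = config$elitism,
    tournament_size = config$tournament_size, seed = config$seed)
  structure(list(
    weights = stats::setNames(res$par, colnames(counts)),
    objective = res$value, degenerate = FALSE,
    convergence = res$convergence, config = config), class = "weight_fit")
}

#' @export
print.weight_fit <- function(x, ...) {
  cat("module weight fit (", x$config$encoding, " encoding)\n", sep = "")
  if (x$degenerate) cat("  DEGENERATE: constant match counts, flat objective\n")
  print(round(x$weights, 3))
  cat("  objective (population variance):", format(x$objective), "\n")
  invisible(x)
}

#' Score a cohort's diagnosis texts
#'
#' Convenience wrapper: counts matches for both text fields, optionally
#' solves weights per category by GA (otherwise uses the library's stored
#' weights), and returns the two diagnostic-score columns.
#'
#' @param cohort Data frame with `primary_dx_text` and `other_dx_text`.
#' @param library A `keyword_library`.
#' @param optimize Solve weights by GA (`TRUE`) or use stored weights.
#' @param config A [ga_config()]; per-category seeds are derived from it.
#' @return List with `scores` (data.frame: `primary_dx_score`,
#'   `other_dx_score`), `fits` (per-category `weight_fit` or stored weights),
#'   `counts` (per-category match matrices).
#' @export
score_cohort_text <- function(cohort, library = default_keyword_library(),
                              optimize = TRUE, config = ga_config()) {
  out_scores <- list()
  fits <- list()
  counts_all <- list()
  fields <- c(primary = "primary_dx_text", other = "other_dx_text")
  for (cat_name in names(fields)) {
    counts <- count_matches(cohort[[fields[[cat_name]]]], library, cat_name)
    if (optimize) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, paste0("weights_", cat_name))
      fit <- optimize_weights(counts, cfg)
      w <- fit$weights
    } else {
      w <- library_weights(library, cat_name)
      if (anyNA(w)) stop("library has unset weights for category ", cat_name)
      fit <- list(weights = w, objective =
                    variance_objective(diagnostic_score(counts, w)))
    }
    out_scores[[paste0(cat_name, "_dx_score")]] <- diagnostic_score(counts, w)
    fits[[cat_name]] <- fit
    counts_all[[cat_name]] <- counts
  }
  list(scores = as.data.frame(out_scores), fits = fits, counts = counts_all)
}
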