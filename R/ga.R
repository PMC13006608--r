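#' Genetic-algorithm maximizer over a box
#'
#' A generational GA with tournament selection, uniform crossover, per-gene
#' mutation, elitism, and two stock diversity devices for box-constrained
#' deceptive landscapes: boundary mutation (a mutated gene jumps to a box
#' bound half the time) and random immigrants (a small fraction of each
#' generation is drawn fresh). Used both to solve keyword-module weights
#' (integer genes in 0..5) and to tune model hyperparameters (mixed
#' integer/continuous genes). Maximizes `fitness`.
#'
#' @param fitness Function taking a numeric gene vector, returning a scalar
#'   to maximize. Must be deterministic.
#' @param lower,upper Numeric vectors of per-gene bounds (equal length).
#' @param integer Logical vector (recycled): which genes are integer-valued.
#' @param pop_size Population size (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate Probability a mating pair undergoes uniform crossover.
#' @param mutation_rate Per-gene mutation probability.
#' @param elitism Number of best individuals copied unchanged each generation.
#' @param tournament_size Tournament size for parent selection.
#' @param boundary_frac Fraction of mutations that jump to a box bound
#'   instead of resampling uniformly.
#' @param immigrant_frac Fraction of each generation's children replaced by
#'   fresh random individuals.
#' @param seed Optional integer seed.
#' @param init Optional matrix of individuals (rows) to seed the population,
#'   e.g. a known good configuration.
#' @return List with `par` (best genes; ties resolved to the lexicographically
#'   smallest vector seen), `value` (best fitness), `convergence`
#'   (best-so-far fitness per generation) and `evaluations`.
#' @export
ga_optimize <- function(fitness, lower, upper, integer = TRUE,
                        pop_size = 60L, generations = 100L,
                        crossover_rate = 0.8, mutation_rate = 0.1,
                        elitism = 2L, tournament_size = 3L,
                        boundary_frac = 0.5, immigrant_frac = 0.1,
                        seed = NULL, init = NULL) {
  stopifnot(length(lower) == length(upper), all(upper >= lower),
            pop_size >= 2L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_genes <- length(lower)
  integer <- rep_len(integer, n_genes)

  draw_gene <- function(j, n) {
    if (integer[j]) sample(seq(lower[j], upper[j]), n, replace = TRUE)
    else stats::runif(n, lower[j], upper[j])
  }
  pop <- vapply(seq_len(n_genes), function(j) draw_gene(j, pop_size),
                numeric(pop_size))
  pop <- matrix(pop, nrow = pop_size)
  if (!is.null(init)) {
    init <- matrix(as.numeric(init), ncol = n_genes)
    k <- min(nrow(init), pop_size)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }

  evaluate <- function(p) apply(p, 1L, fitness)
  fit <- evaluate(pop)
  n_eval <- pop_size

  best_i <- which.max(fit)
  best_par <- pop[best_i, ]
  best_val <- fit[best_i]
  conv <- numeric(generations)

  for (g in seq_len(generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(min(elitism, pop_size))], , drop = FALSE]

    pick <- function() {
      cand <- sample.int(pop_size, tournament_size, replace = TRUE)
      cand[which.max(fit[cand])]
    }
    n_child <- pop_size - nrow(elite)
    n_imm <- floor(immigrant_frac * n_child)
    n_bred <- n_child - n_imm
    children <- matrix(0, n_child, n_genes)
    i <- 1L
    while (i <= n_bred) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (stats::runif(1) < crossover_rate) {
        mask <- stats::runif(n_genes) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      children[i, ] <- c1
      if (i + 1L <= n_bred) children[i + 1L, ] <- c2
      i <- i + 2L
    }
    if (n_imm > 0L) {
      imm_rows <- seq(n_bred + 1L, n_child)
      for (j in seq_len(n_genes))
        children[imm_rows, j] <- draw_gene(j, n_imm)
    }
    mut <- matrix(stats::runif(n_child * n_genes) < mutation_rate, n_child)
    for (j in seq_len(n_genes)) {
      hit <- which(mut[, j])
      if (length(hit)) {
        to_bound <- stats::runif(length(hit)) < boundary_frac
        vals <- numeric(length(hit))
        if (any(to_bound))
          vals[to_bound] <- ifelse(stats::runif(sum(to_bound)) < 0.5,
                                   lower[j], upper[j])
        if (any(!to_bound)) vals[!to_bound] <- draw_gene(j, sum(!to_bound))
        children[hit, j] <- vals
      }
    }
    pop <- rbind(elite, children)
    fit <- evaluate(pop)
    n_eval <- n_eval + nrow(pop)

    gi <- which.max(fit)
    if (fit[gi] > best_val ||
        (fit[gi] == best_val && lex_less(pop[gi, ], best_par))) {
      best_val <- fit[gi]
      best_par <- pop[gi, ]
    }
    conv[g] <- best_val
  }
  list(par = best_par, value = best_val, convergence = conv,
       evaluations = n_eval)
}
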