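test_that("keyword matching counts module occurrences in normalized text", {
  lib <- default_keyword_library()
  cm <- count_matches("craniocerebral injury; multiple trauma", lib, "primary")
  expect_equal(cm[1, "head_and_brain"], c(head_and_brain = 1L))
  expect_equal(cm[1, "multiple_injuries"], c(multiple_injuries = 1L))
  expect_equal(sum(cm), 2L)

  expect_true(all(count_matches("", lib, "primary") == 0L))
  expect_true(all(count_matches(NA_character_, lib, "other") == 0L))

  # repeated occurrences all count
  cm3 <- count_matches("fracture, fracture and fracture", lib, "primary")
  expect_equal(unname(cm3[1, "fracture_limb_pelvis"]), 3L)

  # case and punctuation are normalized away
  a <- count_matches("Rib Fracture!!", lib, "primary")
  b <- count_matches("rib fracture", lib, "primary")
  expect_identical(a, b)
})

test_that("match counts agree with an independent sliding-window oracle", {
  lib <- default_keyword_library()
  set.seed(42)
  mods <- lib$primary
  vocab <- unlist(lapply(mods, `[[`, "keywords"))
  texts <- replicate(25, paste(
    sample(c(vocab, "observation", "ward", "review"), sample(3:8, 1),
           replace = TRUE), collapse = "; "))
  got <- count_matches(texts, lib, "primary")
  # oracle: scan every start position of the normalized text
  oracle_count <- function(text, kw) {
    tx <- normalize_text(text); kw <- normalize_text(kw)
    n <- nchar(tx); k <- nchar(kw)
    if (k == 0 || n < k) return(0L)
    sum(vapply(seq_len(n - k + 1L),
               function(i) substr(tx, i, i + k - 1L) == kw, logical(1)))
  }
  for (j in seq_along(mods)) {
    expect_equal(
      got[, j],
      vapply(texts, function(tx)
        sum(vapply(mods[[j]]$keywords, oracle_count, integer(1), text = tx)),
        integer(1), USE.NAMES = FALSE),
      info = mods[[j]]$module)
  }
})

test_that("diagnostic score is the weighted sum of match counts", {
  w_tab1 <- c(5, 1, 2, 3, 1, 3, 5)  # reference primary-category weights
  expect_equal(diagnostic_score(rep(0L, 7), w_tab1), 0)
  one_head <- c(1L, 0L, 0L, 0L, 0L, 0L, 0L)
  expect_equal(diagnostic_score(one_head, w_tab1), 5)
  expect_equal(diagnostic_score(c(1L, 0L, 2L, 0L, 0L, 0L, 0L),
                                c(5, 1, 2, 3, 1, 3, 5)), 9)
  expect_error(diagnostic_score(rep(1L, 6), w_tab1), "module")
})

test_that("variance objective is the population variance", {
  expect_equal(variance_objective(c(3, 3, 3)), 0)
  expect_equal(variance_objective(c(0, 10)), 25)  # divisor n, not n-1
  expect_error(variance_objective(numeric(0)), "empty")

  # doubling the weights quadruples the objective
  cm <- random_counts(seed = 5)
  w <- c(1, 2, 0, 3, 1, 5, 2)
  expect_equal(variance_objective(diagnostic_score(cm, 2 * w)),
               4 * variance_objective(diagnostic_score(cm, w)))
})

test_that("weight solver handles degenerate and single-module cases", {
  # J = 1: objective is delta^2 * var(N), monotone -> weight 5
  cm1 <- matrix(c(0L, 1L, 3L, 2L), ncol = 1,
                dimnames = list(NULL, "only"))
  fit1 <- optimize_weights(cm1, ga_config(generations = 20L, seed = 2L))
  expect_equal(unname(fit1$weights), 5)

  # identical columns: any delta1 + delta2 = 10 is optimal; the integer
  # grid admits only (5,5), and the exhaustive tie-break agrees
  cm2 <- cbind(a = c(0L, 2L, 1L, 3L), b = c(0L, 2L, 1L, 3L))
  expect_equal(unname(exhaustive_weight_search(cm2)$weights), c(5, 5))
  fit2 <- optimize_weights(cm2, ga_config(seed = 3L))
  expect_equal(unname(fit2$weights), c(5, 5))

  # all-constant counts -> flat objective, flagged degenerate
  fit0 <- optimize_weights(matrix(2L, 5, 3), ga_config(seed = 1L))
  expect_true(fit0$degenerate)
  expect_equal(fit0$objective, 0)
})

test_that("GA finds the exhaustive-grid optimum and never exceeds it", {
  for (seed in 1:8) {
    cm <- random_counts(seed = seed)
    ex <- exhaustive_weight_search(cm)
    fit <- optimize_weights(cm, ga_config(seed = seed))
    expect_lte(fit$objective, ex$objective + 1e-9)
    expect_equal(fit$objective, ex$objective, tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("the grid optimum lies at a vertex of the weight box", {
  # the objective is a convex quadratic in the weights, so its box maximum
  # is attained at a vertex of [0,5]^J; the integer grid contains them all
  for (seed in c(2, 9)) {
    cm <- random_counts(seed = seed)
    full <- exhaustive_weight_search(cm, levels = 0:5)
    vertex <- exhaustive_weight_search(cm, levels = c(0, 5))
    expect_equal(full$objective, vertex$objective, tolerance = 1e-9)
    expect_true(all(full$weights %in% c(0, 5)))
  }
})

test_that("a keyword that never occurs leaves scores unchanged", {
  lib <- default_keyword_library()
  texts <- c("rib fracture after fall", "concussion noted",
             "splenic rupture; multiple trauma")
  base <- count_matches(texts, lib, "primary")
  lib2 <- lib
  lib2$primary[[3]]$keywords <- c(lib2$primary[[3]]$keywords,
                                  "zzz never present zzz")
  aug <- count_matches(texts, lib2, "primary")
  expect_identical(base, aug)
})

test_that("text scoring is deterministic and seed-reproducible", {
  lib <- default_keyword_library()
  co <- quick_cohort(seed = 3L)
  expect_identical(count_matches(co$primary_dx_text, lib, "primary"),
                   count_matches(co$primary_dx_text, lib, "primary"))
  cm <- random_counts(seed = 4)
  f1 <- optimize_weights(cm, ga_config(seed = 11L))
  f2 <- optimize_weights(cm, ga_config(seed = 11L))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$convergence, f2$convergence)
})

test_that("library validation rejects malformed libraries", {
  lib <- default_keyword_library()
  expect_silent(validate_keyword_library(lib))
  expect_equal(length(library_modules(lib, "primary")), 7L)
  expect_equal(length(library_modules(lib, "other")), 7L)
  bad <- lib
  bad$primary[[2]]$module <- bad$primary[[1]]$module
  expect_error(validate_keyword_library(bad), "duplicate")
  bad2 <- lib
  bad2$other[[1]]$keywords <- character(0)
  expect_error(validate_keyword_library(bad2), "empty keyword")
  bad3 <- lib
  bad3$primary[[1]]$weight <- 7
  expect_error(validate_keyword_library(bad3), "weight")
})
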