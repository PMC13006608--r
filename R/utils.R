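#' Derive a per-stage seed from a global seed
#'
#' Fans a single integer seed out into stage-specific seeds by mixing in a
#' stable hash of the stage label, so each pipeline stage is independently
#' reproducible from the one global seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, nchar(stage) > 0L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 100003
  # stay well below 2^31 so the result is a valid R integer seed
  as.integer((as.numeric(seed) %% 200000 * 10007 + h) %% 2147483629)
}

#' Min-max normalize a numeric vector
#'
#' @param x Numeric vector.
#' @return Vector rescaled to `[0, 1]`; a constant vector maps to all zeros.
#' @keywords internal
minmax_normalize <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen positive case receives a higher score
#' than a randomly chosen negative case, with ties counted 1/2.
#'
#' @param y Binary labels (0/1, logical, or a two-level factor where the
#'   second level is the positive class).
#' @param score Numeric scores, larger = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(y, score) {
  y <- as_binary01(y)
  stopifnot(length(y) == length(score))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes present")
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
as_binary01 <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("binary labels must have exactly two levels")
    return(as.integer(y == levels(y)[2L]))
  }
  if (is.logical(y)) return(as.integer(y))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("binary labels must be coded 0/1")
  y
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples positives and negatives independently and reports percentile
#' bounds of the rank AUC.
#'
#' @param y,score As in [auc_rank()].
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @return Named vector `c(auc, lower, upper)`.
#' @export
auc_ci <- function(y, score, n_boot = 1000L, level = 0.95, seed = NULL) {
  y <- as_binary01(y)
  if (!is.null(seed)) set.seed(seed)
  pos <- which(y == 1L); neg <- which(y == 0L)
  est <- auc_rank(y, score)
  if (n_boot < 2L) return(c(auc = est, lower = NA_real_, upper = NA_real_))
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auc_rank(y[idx], score[idx])
  }, numeric(1))
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(auc = est, lower = qs[1], upper = qs[2])
}

#' Stratified k-fold assignment
#'
#' @param y Class labels (factor or vector).
#' @param k Number of folds.
#' @param seed Optional seed.
#' @return Integer vector of fold ids in `1..k`, stratified by class.
#' @export
stratified_folds <- function(y, k = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Statistical mode (most frequent value)
#' @param x A vector; NAs are ignored.
#' @return The most frequent value; ties break toward the first-sorted value.
#' @keywords internal
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  tab <- sort(table(x), decreasing = TRUE)
  v <- names(tab)[1L]
  if (is.numeric(x)) as.numeric(v) else if (is.integer(x)) as.integer(v) else v
}

#' Write an R object as pretty JSON
#' @keywords internal
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Compare two numeric vectors lexicographically
#' @return TRUE when `a` precedes `b`.
#' @keywords internal
lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  if (!length(i)) return(FALSE)
  d[i[1]] < 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
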