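#' The six AIS body regions used by the composite scores
#' @return Character vector of region identifiers, fixed order.
#' @export
ais_regions <- function() {
  c("head_neck", "face", "chest", "limbs_pelvis", "abdomen_pelvis",
    "body_surface")
}

check_ais <- function(ais) {
  ais <- as.matrix(ais)
  if (ncol(ais) != 6L) stop("AIS matrix must have six region columns")
  if (anyNA(ais) || !all(ais %in% 0:6))
    stop("AIS entries must be integers in 0..6")
  if (is.null(colnames(ais))) colnames(ais) <- ais_regions()
  ais
}

#' CRITIC objective weights for the six AIS regions
#'
#' CRITIC (CRiteria Importance Through Intercriteria Correlation) weights a
#' criterion by the product of its dispersion and its decorrelation from the
#' other criteria. Each column is min-max normalized; its variability `S_j`
#' is the sample standard deviation of the normalized column; its conflict
#' `R_j = sum_k (1 - r_jk)` over Pearson correlations with every column (the
#' self term contributes 0); the information amount is `C_j = S_j * R_j` and
#' weights are `w_j = C_j / sum(C)`.
#'
#' A constant column carries no information: it gets `S_j = 0`, `w_j = 0`
#' and is flagged; its (undefined) correlations with other columns are
#' treated as 0.
#'
#' @param ais Patients x 6 matrix of integer AIS values in 0..6.
#' @return A data.frame of class `critic_table` with columns `region`,
#'   `variability`, `conflict`, `information`, `weight`, `flagged`.
#' @export
critic_weights <- function(ais) {
  ais <- check_ais(ais)
  if (nrow(ais) < 3L) stop("need at least 3 patients")
  Z <- apply(ais, 2L, minmax_normalize)
  S <- apply(Z, 2L, stats::sd)
  constant <- S == 0
  r <- suppressWarnings(stats::cor(Z))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  R <- colSums(1 - r)
  C <- S * R
  w <- if (sum(C) > 0) C / sum(C) else rep(0, length(C))
  structure(data.frame(region = colnames(ais), variability = S,
                       conflict = R, information = C, weight = w,
                       flagged = constant, row.names = NULL),
            class = c("critic_table", "data.frame"))
}

#' Equal-weight composite AIS
#'
#' Mean of the six regional AIS values (weight 1/6 = 0.167 each).
#'
#' @inheritParams critic_weights
#' @return Numeric per-patient composite.
#' @export
equal_weight_composite <- function(ais) {
  ais <- check_ais(ais)
  rowMeans(ais)
}

#' Injury Severity Score
#'
#' Sum of squares of the three highest regional AIS values; by the standard
#' convention any region scored 6 (currently untreatable injury) sets
#' ISS = 75. Range 0..75.
#'
#' @inheritParams critic_weights
#' @return Integer vector of ISS values.
#' @export
iss_score <- function(ais) {
  ais <- check_ais(ais)
  apply(ais, 1L, function(row) {
    if (any(row == 6L)) return(75L)
    top <- sort(row, decreasing = TRUE)[1:3]
    as.integer(sum(top^2))
  })
}

#' Weighted composite AIS
#'
#' @inheritParams critic_weights
#' @param weights Non-negative length-6 weight vector.
#' @return Numeric per-patient composite (row dot products).
#' @export
weighted_composite <- function(ais, weights) {
  ais <- check_ais(ais)
  weights <- as.numeric(weights)
  if (length(weights) != 6L) stop("weights must have length 6")
  if (any(weights < 0)) stop("weights must be non-negative")
  as.numeric(ais %*% weights)
}

#' Hosmer-Lemeshow goodness-of-calibration test
#'
#' Groups predictions into `g` risk bins (deciles of predicted probability by
#' default) and compares observed vs expected event counts; the statistic is
#' referred to a chi-square with `g - 2` degrees of freedom.
#'
#' @param y Binary outcomes (0/1).
#' @param p Predicted probabilities.
#' @param g Number of bins.
#' @return List with `statistic`, `df`, `p_value`, `bins` (per-bin table).
#' @export
hosmer_lemeshow <- function(y, p, g = 10L) {
  y <- as_binary01(y)
  stopifnot(length(y) == length(p), all(p >= 0 & p <= 1))
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1)))
  bin <- cut(p, breaks = br, include.lowest = TRUE)
  obs <- tapply(y, bin, sum)
  n <- tapply(y, bin, length)
  exp_ <- tapply(p, bin, sum)
  keep <- !is.na(n) & n > 0
  obs <- obs[keep]; n <- n[keep]; exp_ <- exp_[keep]
  denom <- exp_ * (1 - exp_ / n)
  denom[denom < .Machine$double.eps] <- NA
  stat <- sum((obs - exp_)^2 / denom, na.rm = TRUE)
  df <- max(length(obs) - 2L, 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       bins = data.frame(n = as.integer(n), observed = as.integer(obs),
                         expected = as.numeric(exp_)))
}

#' Decision-curve analysis net benefit
#'
#' `NB(p_t) = TP/n - (FP/n) * p_t / (1 - p_t)` with classification rule
#' `p >= p_t`. Also returns the treat-all policy (which crosses zero at the
#' prevalence) and treat-none (identically 0).
#'
#' @param y Binary outcomes (0/1).
#' @param p Predicted probabilities.
#' @param thresholds Decision-threshold grid.
#' @return Data frame: `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(y, p, thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- as_binary01(y)
  n <- length(y)
  prev <- mean(y)
  out <- t(vapply(thresholds, function(pt) {
    pred <- p >= pt
    tp <- sum(pred & y == 1L) / n
    fp <- sum(pred & y == 0L) / n
    odds <- pt / (1 - pt)
    c(tp - fp * odds, prev - (1 - prev) * odds)
  }, numeric(2)))
  data.frame(threshold = thresholds, net_benefit = out[, 1],
             treat_all = out[, 2], treat_none = 0)
}

#' Compare composite-AIS weighting schemes
#'
#' Computes the CRITIC-weighted, equal-weight and ISS composites, calibrates
#' each with a univariate logistic model against the binary outcome and
#' reports discrimination (AUC), Hosmer-Lemeshow calibration and the decision
#' curve. For ISS the reported per-region "weights" are the average share each
#' region contributes to the ISS sum (the score itself is not a weighted sum).
#'
#' @inheritParams critic_weights
#' @param outcome Binary outcome (1 = poor prognosis).
#' @param hl_bins Hosmer-Lemeshow bin count.
#' @return List of class `scheme_comparison`: per scheme `weights`,
#'   `composite`, `auc`, `hl` and `dca`; plus the full `critic` table.
#' @export
compare_schemes <- function(ais, outcome, hl_bins = 10L) {
  ais <- check_ais(ais)
  y <- as_binary01(outcome)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  crit <- critic_weights(ais)

  iss <- iss_score(ais)
  sq <- ais^2
  top3 <- t(apply(ais, 1L, function(row) {
    keep <- rank(-row, ties.method = "first") <= 3
    row^2 * keep
  }))
  share <- colSums(top3)
  iss_share <- if (sum(share) > 0) share / sum(share) else rep(NA_real_, 6L)

  schemes <- list(
    critic = list(weights = stats::setNames(crit$weight, crit$region),
                  composite = weighted_composite(ais, crit$weight)),
    equal = list(weights = stats::setNames(rep(1 / 6, 6L), colnames(ais)),
                 composite = equal_weight_composite(ais)),
    iss = list(weights = iss_share, composite = as.numeric(iss))
  )
  for (nm in names(schemes)) {
    comp <- schemes[[nm]]$composite
    fit <- stats::glm(y ~ comp, family = stats::binomial())
    prob <- stats::fitted(fit)
    schemes[[nm]]$auc <- auc_rank(y, comp)
    schemes[[nm]]$hl <- hosmer_lemeshow(y, prob, g = hl_bins)
    schemes[[nm]]$dca <- decision_curve(y, prob)
  }
  structure(c(schemes, list(critic_table = crit)),
            class = "scheme_comparison")
}

#' Load the RTS/TRISS coefficient configuration
#'
#' Standard published coefficient sets for the Revised Trauma Score and the
#' TRISS survival model, kept as configuration data rather than in-code
#' constants.
#'
#' @param path Optional path to an alternative JSON coefficient file.
#' @return Nested list with `rts` and `triss` components.
#' @export
trauma_score_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trauma_score_coefficients.json",
                        package = "traumaprog", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Revised Trauma Score from coded physiology
#'
#' @param gcs,sbp,rr Integer category codes 0..4 for Glasgow Coma Scale,
#'   systolic blood pressure and respiratory rate.
#' @param coefficients RTS coefficient list (see
#'   [trauma_score_coefficients()]).
#' @return Numeric RTS values (0 to ~7.84).
#' @export
rts_score <- function(gcs, sbp, rr,
                      coefficients = trauma_score_coefficients()$rts) {
  codes <- cbind(gcs, sbp, rr)
  if (anyNA(codes) || !all(codes %in% 0:4))
    stop("RTS category codes must be integers in 0..4")
  coefficients$gcs * gcs + coefficients$sbp * sbp + coefficients$rr * rr
}

#' TRISS survival probability
#'
#' Logistic model `P = plogis(b0 + b1*RTS + b2*ISS + b3*AgeIndex)` with the
#' standard blunt or penetrating coefficient set.
#'
#' @param rts RTS values.
#' @param iss ISS values.
#' @param age_index 0 (age < 55) or 1 (age >= 55).
#' @param mechanism `"blunt"` or `"penetrating"`.
#' @param coefficients TRISS coefficient list.
#' @return Predicted survival probabilities.
#' @export
triss_probability <- function(rts, iss, age_index,
                              mechanism = c("blunt", "penetrating"),
                              coefficients = trauma_score_coefficients()$triss) {
  mechanism <- match.arg(mechanism)
  if (!all(age_index %in% 0:1)) stop("age_index must be 0 or 1")
  b <- coefficients[[mechanism]]
  stats::plogis(b$b0 + b$b1 * rts + b$b2 * iss + b$b3 * age_index)
}
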