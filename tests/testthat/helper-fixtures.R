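# shared fixture builders; everything is generated in code at test time

quick_cohort <- function(n_cure = 40L, n_improved = 50L, n_poor = 25L,
                         seed = 1L, missing_rate = 0.02) {
  generate_cohort(cohort_spec(n_cure = n_cure, n_improved = n_improved,
                              n_poor = n_poor, missing_rate = missing_rate,
                              seed = seed))
}

# small match-count matrices with negative inter-module correlation
# (multinomial allocation), the interesting regime for the weight solver
random_counts <- function(n = 30L, J = 7L, seed = 1L, size = 8L) {
  set.seed(seed)
  t(stats::rmultinom(n, size = size, prob = stats::runif(J, 0.5, 1.5)))
}

# numeric design for model tests: n x p standard normal columns
random_design <- function(n, p, seed = 1L, prefix = "x") {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * p), n, p)
  colnames(m) <- paste0(prefix, seq_len(p))
  as.data.frame(m)
}

table3_reference <- function() {
  utils::read.csv(system.file("extdata", "critic_reference.csv",
                              package = "traumaprog"))
}

table5_sets <- function() {
  jsonlite::read_json(system.file("extdata", "screened_features.json",
                                  package = "traumaprog"),
                      simplifyVector = TRUE)
}

table7_reference <- function() {
  utils::read.csv(system.file("extdata", "stepwise_reference.csv",
                              package = "traumaprog"))
}
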