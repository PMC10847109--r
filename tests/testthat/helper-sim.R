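# Small configurations used across tests: full causal structure at sizes
# that keep individual tests fast.

small_config <- function(seed = 1, ...) {
  sim_config(n_females = 2000, n_males = 1500, n_snps_per_exposure = 10,
             seed = seed, ...)
}

# Independent weighted-least-squares oracles for the MR estimators, coded
# via stats::lm so they share nothing with the closed-form implementations.
oracle_ivw <- function(set) {
  f <- stats::lm(by ~ 0 + bx, data = set, weights = 1 / set$byse^2)
  unname(coef(f)[1])
}

oracle_egger <- function(set) {
  s <- ifelse(set$bx < 0, -1, 1)
  d <- data.frame(bx = s * set$bx, by = s * set$by)
  f <- stats::lm(by ~ bx, data = d, weights = 1 / set$byse^2)
  c(intercept = unname(coef(f)[1]), slope = unname(coef(f)[2]))
}

oracle_mvivw <- function(set) {
  f <- stats::lm(by ~ 0 + bx + bx2, data = set, weights = 1 / set$byse^2)
  unname(coef(f))
}

random_set <- function(k = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    snp = sprintf("s%03d", seq_len(k)),
    bx = rnorm(k, 0.05, 0.03), bxse = runif(k, 0.002, 0.01),
    by = rnorm(k, 0.01, 0.02), byse = runif(k, 0.005, 0.02),
    bx2 = rnorm(k, 0.02, 0.02)
  )
}
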