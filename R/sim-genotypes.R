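# Genotype simulation: independent SNPs in Hardy-Weinberg equilibrium.
# Instruments are modelled LD-free, matching the pruned instrument lists the
# MR design consumes.

# Internal: draw an n x k dosage matrix. When `strat` is supplied with a
# non-zero effect, per-individual allele frequencies are shifted on the
# logit scale, inducing genotype-ancestry correlation.
.draw_genotypes <- function(n, mafs, strat = NULL, strat_effect = 0) {
  k <- length(mafs)
  if (!is.null(strat) && strat_effect != 0) {
    p <- stats::plogis(outer(strat_effect * strat, stats::qlogis(mafs), "+"))
    g <- matrix(stats::rbinom(n * k, 2L, p), nrow = n, ncol = k)
  } else {
    g <- matrix(stats::rbinom(n * k, 2L, rep(mafs, each = n)),
                nrow = n, ncol = k)
  }
  g
}

# Internal: random effect/other allele pair per SNP (palindromic pairs arise
# naturally, exercising the harmonization rules).
.draw_alleles <- function(k) {
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, k, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), character(1L),
               USE.NAMES = FALSE)
  data.frame(ea = ea, oa = oa, stringsAsFactors = FALSE)
}

#' Simulate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Draws `n_snps_per_exposure` independent SNPs for `n_females` individuals,
#' each with an effect-allele frequency uniform on `maf_range`, dosages
#' binomial(2, p). Reproducible under the configuration seed.
#'
#' @param config a [sim_config()] object.
#' @param n number of individuals; defaults to `config$n_females`.
#' @return integer matrix (individuals x SNPs) with entries in \{0, 1, 2\},
#'   column names `rs_0001`, ..., and attributes `ea`, `oa`, `maf`.
#' @export
simulate_genotypes <- function(config, n = config$n_females) {
  config <- validate_sim_config(config)
  if (n < 1L) stop("configuration error: n must be positive")
  set.seed(config$seed)
  k <- config$n_snps_per_exposure
  mafs <- stats::runif(k, config$maf_range[1], config$maf_range[2])
  g <- .draw_genotypes(n, mafs)
  al <- .draw_alleles(k)
  colnames(g) <- sprintf("rs_%04d", seq_len(k))
  attr(g, "ea") <- al$ea
  attr(g, "oa") <- al$oa
  attr(g, "maf") <- mafs
  g
}

# Internal: per-SNP effects with half-normal heterogeneous magnitudes
# (GWAS hits vary in size; the spread also identifies the Egger slope),
# random signs, jointly rescaled so the additive score explains exactly
# `r2` of `var_trait`.
.instrument_effects <- function(r2, var_trait, mafs) {
  k <- length(mafs)
  raw <- abs(stats::rnorm(k)) + 0.2   # avoid near-null instruments
  beta <- raw * sample(c(-1, 1), k, replace = TRUE)
  scale <- sqrt(r2 * var_trait / sum(2 * mafs * (1 - mafs) * beta^2))
  beta * scale
}
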