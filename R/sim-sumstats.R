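# GWAS summary statistics: computed from individual-level data by per-SNP
# least squares, or simulated analytically at arbitrary GWAS sample sizes.

#' Per-SNP association summary statistics
#'
#' Regresses the phenotype on each allele count (plus covariates) by ordinary
#' least squares and returns one record per SNP. Covariates are projected out
#' once, so the per-SNP pass is a vectorised simple regression on residuals -
#' numerically identical to fitting `phenotype ~ snp + covariates` SNP by SNP.
#'
#' @param genotypes dosage matrix (individuals x SNPs) with optional allele
#'   attributes as produced by [simulate_genotypes()] /
#'   [simulate_cohort()].
#' @param phenotype numeric vector, one value per genotype row.
#' @param covariates optional data.frame of covariates (complete, no `NA`s).
#' @return data.frame with columns `SNP`, `EA`, `OA`, `EAF`, `BETA`, `SE`,
#'   `P`, `N` and `monomorphic`; monomorphic SNPs are flagged and carry `NA`
#'   estimates (their SE is undefined).
#' @export
compute_summary_stats <- function(genotypes, phenotype, covariates = NULL) {
  g <- as.matrix(genotypes)
  n <- nrow(g)
  if (length(phenotype) != n)
    stop("phenotype length must equal the number of genotype rows")
  if (anyNA(phenotype)) stop("phenotype must be complete")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must match genotype rows")
    if (anyNA(covariates)) stop("covariates must be complete")
    M <- stats::model.matrix(~ ., data = covariates)
  } else {
    M <- matrix(1, n, 1L)
  }
  qrM <- qr(M)
  p <- qrM$rank
  ry <- qr.resid(qrM, phenotype)
  rg <- qr.resid(qrM, g)
  sxx <- colSums(rg^2)
  mono <- sxx < 1e-10
  beta <- colSums(rg * ry) / sxx
  df <- n - p - 1L
  rss <- sum(ry^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  beta[mono] <- NA_real_; se[mono] <- NA_real_; pval[mono] <- NA_real_
  ea <- attr(genotypes, "ea")
  oa <- attr(genotypes, "oa")
  out <- data.frame(
    SNP = if (!is.null(colnames(g))) colnames(g) else
      sprintf("snp_%04d", seq_len(ncol(g))),
    EA = if (!is.null(ea)) ea else NA_character_,
    OA = if (!is.null(oa)) oa else NA_character_,
    EAF = colMeans(g) / 2,
    BETA = beta, SE = se, P = pval, N = n,
    monomorphic = mono,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Simulate instrument summary statistics at GWAS scale
#'
#' Analytic simulation of a published instrument table: per-SNP effects with
#' equal expected variance contributions summing to `r2` of the trait
#' variance, estimates perturbed by the sampling error implied by the GWAS
#' sample size (`SE ~ sqrt(var / (2 p (1-p) n))`). Avoids materialising
#' genotypes for hundreds of thousands of individuals.
#'
#' @param n_snps number of instruments (e.g. 389 menarche, 32 parity, 290
#'   menopause).
#' @param r2 total variance fraction explained (e.g. 0.074, 0.002, 0.082).
#' @param n GWAS sample size (e.g. 329345, 785604, 496151).
#' @param trait_variance phenotypic variance on the reported scale.
#' @param maf_range effect-allele frequency range.
#' @param seed optional integer seed.
#' @param prefix SNP identifier prefix.
#' @return summary-statistic data.frame (`SNP`, `EA`, `OA`, `EAF`, `BETA`,
#'   `SE`, `P`, `N`) with attribute `true_beta`.
#' @export
simulate_instrument_stats <- function(n_snps, r2, n, trait_variance = 1,
                                      maf_range = c(0.05, 0.5), seed = NULL,
                                      prefix = "rs") {
  if (!is.null(seed)) set.seed(seed)
  if (n_snps < 1L || n < 3L) stop("configuration error: non-positive counts")
  mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
  beta_true <- .instrument_effects(r2, trait_variance, mafs)
  se <- sqrt(trait_variance / (2 * mafs * (1 - mafs) * n))
  beta <- beta_true + stats::rnorm(n_snps, 0, se)
  al <- .draw_alleles(n_snps)
  out <- data.frame(
    SNP = sprintf("%s_%04d", prefix, seq_len(n_snps)),
    EA = al$ea, OA = al$oa, EAF = mafs,
    BETA = beta, SE = se, P = 2 * stats::pnorm(-abs(beta / se)), N = n,
    stringsAsFactors = FALSE
  )
  attr(out, "true_beta") <- beta_true
  out
}

#' Simulate a harmonized two-sample MR instance
#'
#' Draws instrument-exposure and instrument-outcome association estimates for
#' a known causal effect, with optional invalid (pleiotropic) instruments,
#' directly on the summary-statistic scale used by the two-sample MR
#' estimators. Sampling errors are those implied by the exposure- and
#' outcome-GWAS sample sizes.
#'
#' @param n_snps number of instruments.
#' @param beta true causal effect (outcome SD per exposure unit).
#' @param r2 exposure variance explained by the instrument set.
#' @param n_exposure,n_outcome GWAS sample sizes for the two samples.
#' @param prop_invalid fraction of instruments with direct outcome effects.
#' @param pleio_mean,pleio_sd mean and SD of the direct effects
#'   (`pleio_mean != 0` gives directional pleiotropy; the mean-zero case is
#'   balanced and preserves the InSIDE condition).
#' @param var_exposure,var_outcome phenotypic variances of the two traits.
#' @param maf_range allele-frequency range.
#' @param seed optional integer seed.
#' @return `"harmonized_set"` data.frame (`snp`, `bx`, `bxse`, `by`, `byse`,
#'   `eaf`, `flipped`) with attributes `true_beta` and `invalid` (logical
#'   per-SNP).
#' @export
simulate_summary_mr <- function(n_snps = 100L, beta = 0.1, r2 = 0.074,
                                n_exposure = 50000L, n_outcome = 50000L,
                                prop_invalid = 0, pleio_mean = 0,
                                pleio_sd = 0, var_exposure = 1,
                                var_outcome = 1, maf_range = c(0.1, 0.4),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
  bx_true <- abs(.instrument_effects(r2, var_exposure, mafs))
  bxse <- sqrt(var_exposure / (2 * mafs * (1 - mafs) * n_exposure))
  bx <- bx_true + stats::rnorm(n_snps, 0, bxse)
  invalid <- rep(FALSE, n_snps)
  alpha <- numeric(n_snps)
  n_inv <- round(prop_invalid * n_snps)
  if (n_inv > 0) {
    invalid[sample.int(n_snps, n_inv)] <- TRUE
    alpha[invalid] <- stats::rnorm(n_inv, pleio_mean, pleio_sd)
  }
  byse <- sqrt(var_outcome / (2 * mafs * (1 - mafs) * n_outcome))
  by <- beta * bx_true + alpha + stats::rnorm(n_snps, 0, byse)
  set <- data.frame(
    snp = sprintf("sim_%04d", seq_len(n_snps)),
    bx = bx, bxse = bxse, by = by, byse = byse,
    eaf = mafs, flipped = FALSE, stringsAsFactors = FALSE
  )
  attr(set, "true_beta") <- beta
  attr(set, "invalid") <- invalid
  class(set) <- c("harmonized_set", "data.frame")
  set
}

#' Read / write tab-delimited GWAS summary statistics
#'
#' Plain tab-delimited text with header `SNP EA OA EAF BETA SE P N`.
#'
#' @param path file path.
#' @param x summary-statistic data.frame.
#' @return `read_sumstats` returns the data.frame; `write_sumstats` returns
#'   `path` invisibly.
#' @export
read_sumstats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_sumstats(x, path)
  x
}

#' @rdname read_sumstats
#' @export
write_sumstats <- function(x, path) {
  .check_sumstats(x, "summary statistics")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort table as CSV with a JSON schema sidecar
#'
#' The sidecar (`<file>.schema.json`) records column names and types so the
#' CSV round-trips with stable factor levels. Requires the `jsonlite`
#' package.
#'
#' @param cohort cohort data.frame (the `cohort` element of a
#'   [simulate_cohort()] result).
#' @param path CSV file path.
#' @return `read_cohort` returns the data.frame; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_cohort requires the jsonlite package")
  schema <- lapply(cohort, function(col) {
    if (is.factor(col)) list(type = "factor", levels = levels(col))
    else list(type = class(col)[1L])
  })
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("read_cohort requires the jsonlite package")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".schema.json")
  if (file.exists(sidecar)) {
    schema <- jsonlite::read_json(sidecar)
    for (nm in names(schema)) {
      if (identical(schema[[nm]]$type, "factor"))
        x[[nm]] <- factor(x[[nm]], levels = unlist(schema[[nm]]$levels))
      if (identical(schema[[nm]]$type, "logical"))
        x[[nm]] <- as.logical(x[[nm]])
    }
  }
  x
}
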