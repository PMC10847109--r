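# One-sample MR on individual-level data: weighted polygenic scores,
# two-stage least squares, the polygenic-score Wald ratio, and the
# selected- versus full-sample contrast that probes the menopause
# missingness mechanism.

#' Build a weighted polygenic score
#'
#' Per-individual weighted sum of effect-allele counts. Weight alleles are
#' oriented against the genotype matrix's allele attributes; where the
#' weight's effect allele matches the stored other allele (directly or after
#' strand complementing) the dosage is counted as `2 - g`. SNPs absent from
#' the genotype matrix are skipped with a logged count.
#'
#' @param genotypes dosage matrix with `ea`/`oa` attributes (see
#'   [simulate_cohort()]).
#' @param weights data.frame with columns `snp`, `ea`, `weight` (e.g. the
#'   `snps` element of a simulation, using the true or estimated betas).
#' @return numeric score vector with attributes `n_used` and `n_skipped`.
#' @export
build_pgs <- function(genotypes, weights) {
  need <- c("snp", "ea", "weight")
  miss <- setdiff(need, names(weights))
  if (length(miss))
    stop("weights lack column(s): ", paste(miss, collapse = ", "))
  cols <- colnames(genotypes)
  idx <- match(weights$snp, cols)
  skipped <- sum(is.na(idx))
  if (skipped) message("skipping ", skipped, " weight SNP(s) absent from genotypes")
  use <- !is.na(idx)
  if (!any(use)) stop("no usable SNPs: weights do not match genotype columns")
  idx <- idx[use]
  w <- weights$weight[use]
  wea <- toupper(weights$ea[use])
  gea <- toupper(attr(genotypes, "ea")[idx])
  goa <- toupper(attr(genotypes, "oa")[idx])
  aligned <- wea == gea | wea == .complement(gea)
  flipped <- wea == goa | wea == .complement(goa)
  if (any(!aligned & !flipped)) {
    bad <- sum(!aligned & !flipped)
    message("skipping ", bad, " weight SNP(s) with irreconcilable alleles")
    keep <- aligned | flipped
    idx <- idx[keep]; w <- w[keep]
    aligned <- aligned[keep]; flipped <- flipped[keep]
    skipped <- skipped + bad
    if (!length(idx)) stop("no usable SNPs after allele matching")
  }
  g <- genotypes[, idx, drop = FALSE]
  g[, !aligned] <- 2 - g[, !aligned]
  score <- as.numeric(g %*% w)
  attr(score, "n_used") <- length(idx)
  attr(score, "n_skipped") <- skipped
  score
}

# Internal: complete-case frame for instrument analyses.
.iv_frame <- function(cohort, pgs, exposure_col, outcome, covariates) {
  d <- cohort[, c(exposure_col, outcome, covariates), drop = FALSE]
  d$.pgs <- pgs
  d[stats::complete.cases(d), , drop = FALSE]
}

#' Two-stage least squares with a polygenic-score instrument
#'
#' Stage 1 regresses the exposure on the PGS plus covariates; stage 2
#' regresses the outcome on the fitted exposure plus covariates. Standard
#' errors use the instrumental-variable variance formula, with residuals
#' computed from the observed (not fitted) exposure. The first-stage partial
#' F statistic is reported and a weak-instrument warning is raised below 10.
#'
#' @param cohort cohort data.frame.
#' @param pgs numeric instrument vector aligned with `cohort` rows.
#' @param exposure,outcome column names (or exposure aliases as in
#'   [fit_adjusted_model()]).
#' @param covariates character vector of covariate columns (default none).
#' @return an [effect_estimate()] row (`method = "2sls"`) with attribute
#'   `first_stage_F`.
#' @export
two_stage_least_squares <- function(cohort, pgs, exposure, outcome,
                                    covariates = character(0)) {
  xcol <- .exposure_col(cohort, exposure)
  if (length(pgs) != nrow(cohort))
    stop("`pgs` must have one value per cohort row")
  d <- .iv_frame(cohort, pgs, xcol, outcome, covariates)
  n <- nrow(d)
  if (n < 30L) stop("fewer than 30 complete cases")
  C <- if (length(covariates))
    stats::model.matrix(stats::reformulate(covariates), data = d)
  else matrix(1, n, 1L)
  x <- d[[xcol]]
  y <- d[[outcome]]
  Z <- cbind(C, pgs = d$.pgs)
  xhat <- stats::lsfit(Z, x, intercept = FALSE)$coefficients
  xhat <- as.numeric(Z %*% xhat)
  # first-stage partial F for the instrument
  r_full <- x - xhat
  r_red <- stats::lsfit(C, x, intercept = FALSE)$residuals
  Fstat <- (sum(r_red^2) - sum(r_full^2)) / (sum(r_full^2) / (n - ncol(Z)))
  W <- cbind(C, exposure = xhat)
  b <- solve(crossprod(W), crossprod(W, y))[, 1L]
  Wobs <- cbind(C, exposure = x)
  e <- y - as.numeric(Wobs %*% b)
  sigma2 <- sum(e^2) / (n - ncol(W))
  vc <- sigma2 * solve(crossprod(W))
  est <- effect_estimate(beta = b[["exposure"]],
                         se = sqrt(vc["exposure", "exposure"]),
                         n = n, method = "2sls")
  attr(est, "first_stage_F") <- Fstat
  if (Fstat < 10)
    warning("weak instrument: first-stage F = ", round(Fstat, 1))
  est
}

#' Polygenic-score Wald ratio
#'
#' Ratio of the covariate-adjusted PGS-outcome coefficient to the
#' covariate-adjusted PGS-exposure coefficient, with a delta-method SE that
#' propagates both sampling errors. The exposure association may be
#' estimated on a subsample (`exposure_rows`), e.g. the selected sample of
#' women with an observed age at natural menopause, while the outcome
#' association uses every row - the two-sample variant run on one cohort.
#'
#' @inheritParams two_stage_least_squares
#' @param exposure_rows optional logical/integer index of rows for the
#'   exposure association (default: all rows with observed exposure).
#' @return an [effect_estimate()] row (`method = "pgs_ratio"`) with
#'   attributes `beta_exposure`, `beta_outcome`.
#' @export
pgs_ratio <- function(cohort, pgs, exposure, outcome,
                      covariates = character(0), exposure_rows = NULL) {
  xcol <- .exposure_col(cohort, exposure)
  if (length(pgs) != nrow(cohort))
    stop("`pgs` must have one value per cohort row")
  cohort$.pgs <- pgs
  sub <- if (is.null(exposure_rows)) cohort else
    cohort[exposure_rows, , drop = FALSE]

  reg <- function(data, response) {
    d <- data[, c(response, covariates, ".pgs"), drop = FALSE]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    fit <- stats::lm(stats::reformulate(c(".pgs", covariates),
                                        response = response), data = d)
    sm <- summary(fit)$coefficients
    c(beta = sm[".pgs", 1L], se = sm[".pgs", 2L], n = nrow(d))
  }
  ax <- reg(sub, xcol)
  ay <- reg(cohort, outcome)
  if (abs(ax[["beta"]]) < .Machine$double.eps^0.5)
    stop("PGS-exposure association is zero: ratio undefined")
  bx <- ax[["beta"]]; sx <- ax[["se"]]
  by <- ay[["beta"]]; sy <- ay[["se"]]
  beta <- by / bx
  se <- sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  est <- effect_estimate(beta = beta, se = se, n = ay[["n"]],
                         method = "pgs_ratio")
  attr(est, "beta_exposure") <- ax
  attr(est, "beta_outcome") <- ay
  est
}

#' Selected- versus full-sample contrast for age at natural menopause
#'
#' Runs, for one metabolite, the three analyses whose disagreement
#' diagnoses the missingness mechanism: multivariable regression on the
#' selected sample (women with an observed natural menopause age),
#' two-stage least squares on the selected sample (one-sample MR), and the
#' polygenic-score ratio with the exposure association from the selected
#' sample but the outcome association from all women (two-sample MR on the
#' full sample). When the menopause effect is modified by age and selection
#' is age-linked, the full-sample MR estimate diverges from the
#' selected-sample pair.
#'
#' @param sim a `"cohort_sim"` object from [simulate_cohort()].
#' @param metabolite outcome column name.
#' @param model adjustment model for the regression arm, default
#'   `"model2"`.
#' @param covariates covariates for the MR arms (default none, mirroring a
#'   genotyping-batch/PC adjustment that the simulation does not need).
#' @param weights PGS weights; defaults to the generator's menopause
#'   instrument table.
#' @return list of class `"selection_contrast"`: `mv_selected`,
#'   `tsls_selected`, `ratio_full` (effect-estimate rows), `n_selected`,
#'   `n_full`, `degenerate` (no premenopausal rows).
#' @export
selected_vs_full_contrast <- function(sim, metabolite,
                                      model = "model2",
                                      covariates = character(0),
                                      weights = NULL) {
  if (!inherits(sim, "cohort_sim"))
    stop("`sim` must be a cohort_sim object")
  fem <- sim$cohort[sim$cohort$sex == "female", , drop = FALSE]
  if (is.null(fem$menopause_status)) stop("cohort lacks `menopause_status`")
  if (is.null(weights)) {
    s <- sim$snps$menopause
    weights <- data.frame(snp = s$snp, ea = s$ea, weight = s$beta,
                          stringsAsFactors = FALSE)
  }
  pgs <- build_pgs(sim$genotypes$menopause, weights)
  degenerate <- !any(fem$menopause_status == "pre", na.rm = TRUE)
  if (degenerate)
    warning("no premenopausal rows: selected and full samples coincide")
  selected <- !is.na(fem$menopause_age)
  mv <- fit_adjusted_model(fem[selected, , drop = FALSE], "menopause",
                           metabolite, model)
  tsls <- two_stage_least_squares(fem[selected, , drop = FALSE],
                                  pgs[selected], "menopause", metabolite,
                                  covariates)
  ratio <- pgs_ratio(fem, pgs, "menopause", metabolite, covariates,
                     exposure_rows = selected)
  structure(list(mv_selected = mv, tsls_selected = tsls, ratio_full = ratio,
                 n_selected = sum(selected), n_full = nrow(fem),
                 degenerate = degenerate),
            class = "selection_contrast")
}
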