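# Two-sample summary-data MR estimators. All are closed-form weighted
# least squares; tests cross-check them against independently coded oracles.

.as_set <- function(set) {
  need <- c("bx", "bxse", "by", "byse")
  miss <- setdiff(need, names(set))
  if (length(miss))
    stop("harmonized set lacks column(s): ", paste(miss, collapse = ", "))
  set
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = by / bx` with first-order delta-method standard error
#' `|byse / bx|` (uncertainty in the instrument-exposure association is
#' ignored, the convention for strong instruments).
#'
#' @param bx,bxse instrument-exposure association and its SE.
#' @param by,byse instrument-outcome association and its SE.
#' @return an `"mr_estimate"` row with `method = "wald"`.
#' @export
wald_ratio <- function(bx, bxse, by, byse) {
  if (bx == 0) stop("Wald ratio undefined: instrument-exposure beta is zero")
  mr_estimate(beta = by / bx, se = abs(byse / bx), method = "wald", k_snps = 1L)
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin with weights `1/byse^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`. The fixed-effect SE is
#' `1/sqrt(sum(w bx^2))`; under multiplicative random effects (the default)
#' it is inflated by `sqrt(max(1, Q/(k-1)))` where `Q` is Cochran's
#' heterogeneity statistic.
#'
#' @param set a `"harmonized_set"` (or data.frame with `bx`, `bxse`, `by`,
#'   `byse`), from [harmonise()] or [simulate_summary_mr()].
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `"mr_estimate"` row with Cochran's Q and its df.
#' @export
mr_ivw <- function(set, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  set <- .as_set(set)
  k <- nrow(set)
  if (k < 2L) stop("IVW needs >= 2 SNPs; use wald_ratio() for one instrument")
  w <- 1 / set$byse^2
  beta <- sum(w * set$bx * set$by) / sum(w * set$bx^2)
  se_fixed <- sqrt(1 / sum(w * set$bx^2))
  q <- sum(w * (set$by - beta * set$bx)^2)
  q_df <- k - 1L
  se <- if (mode == "fixed") se_fixed else
    se_fixed * sqrt(max(1, q / q_df))
  mr_estimate(beta, se, method = if (mode == "fixed") "ivw_fixed" else
    "ivw_mre", k_snps = k, cochran_q = q, q_df = q_df)
}

#' MR-Egger regression
#'
#' Weighted least squares of `by` on `bx` with an unconstrained intercept
#' (weights `1/byse^2`), after orienting all instruments so `bx >= 0`.
#' The intercept estimates average directional pleiotropy under the InSIDE
#' assumption; the slope is the pleiotropy-adjusted causal estimate. SEs are
#' the weighted-least-squares ones, with the residual variance estimated
#' from the Egger fit itself.
#'
#' @inheritParams mr_ivw
#' @return list with elements `slope` and `intercept`, each an
#'   `"mr_estimate"` row.
#' @export
mr_egger <- function(set) {
  set <- .as_set(set)
  k <- nrow(set)
  if (k < 3L) stop("MR-Egger needs >= 3 SNPs")
  sgn <- ifelse(set$bx < 0, -1, 1)
  bx <- sgn * set$bx
  by <- sgn * set$by
  if (max(bx) == min(bx))
    stop("MR-Egger slope unidentified: all oriented bx equal")
  w <- 1 / set$byse^2
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  inter <- (swxx * swy - swx * swxy) / denom
  resid <- by - inter - slope * bx
  q <- sum(w * resid^2)
  q_df <- k - 2L
  phi <- q / q_df   # unrestricted WLS residual variance
  se_slope <- sqrt(phi * sw / denom)
  se_inter <- sqrt(phi * swxx / denom)
  list(
    slope = mr_estimate(slope, se_slope, method = "egger", k_snps = k,
                        cochran_q = q, q_df = q_df),
    intercept = mr_estimate(inter, se_inter, method = "egger_intercept",
                            k_snps = k, cochran_q = q, q_df = q_df)
  )
}

# Internal: weighted median of ratio estimates by linear interpolation of the
# weighted empirical CDF at 0.5, using midpoints p_j = (S_j - w_j/2) / sum(w).
.weighted_median <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1L]) return(r[1L])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR estimate
#'
#' Orders per-SNP Wald ratios and takes the weighted median (inverse-variance
#' weights from the first-order delta-method variance of each ratio,
#' interpolating the weighted empirical CDF at 0.5). Consistent when at least
#' half the weight comes from valid instruments. The SE comes from a seeded
#' parametric bootstrap: `bx` and `by` are redrawn from normal distributions
#' centred on their estimates with their reported SEs.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap draws for the SE, default 1000.
#' @param seed integer seed for the bootstrap; `NULL` uses the current RNG
#'   state.
#' @return an `"mr_estimate"` row with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed = NULL) {
  set <- .as_set(set)
  drop <- set$bx == 0
  if (any(drop)) {
    message("dropping ", sum(drop), " SNP(s) with zero exposure beta")
    set <- set[!drop, , drop = FALSE]
  }
  k <- nrow(set)
  if (k < 3L) stop("weighted median needs >= 3 SNPs")
  if (n_boot < 100L) warning("n_boot < 100: bootstrap SE will be unstable")
  # canonical row order so results are invariant to input permutation
  ord <- if ("snp" %in% names(set)) order(set$snp) else order(set$bx, set$by)
  set <- set[ord, , drop = FALSE]
  ratios <- set$by / set$bx
  vr <- set$byse^2 / set$bx^2        # first-order delta-method variance
  wts <- 1 / vr
  est <- .weighted_median(ratios, wts)

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  bxs <- matrix(stats::rnorm(k * n_boot, set$bx, set$bxse), nrow = k)
  bys <- matrix(stats::rnorm(k * n_boot, set$by, set$byse), nrow = k)
  boots <- vapply(seq_len(n_boot), function(b) {
    rb <- bys[, b] / bxs[, b]
    .weighted_median(rb, bxs[, b]^2 / set$byse^2)
  }, numeric(1L), USE.NAMES = FALSE)
  se <- stats::sd(boots)
  mr_estimate(est, se, method = "weighted_median", k_snps = k)
}

#' Multivariable IVW MR
#'
#' Weighted least squares of `by` on the exposure-beta columns without an
#' intercept (weights `1/byse^2`), estimating each exposure's direct effect
#' conditional on the co-exposures. The canonical use is the direct effect of
#' age at menarche on a metabolite accounting for adult BMI.
#'
#' @param set a `"harmonized_set"` with columns `bx` and `bx2` (from
#'   [harmonise_mv()]), or any data.frame with those columns plus `byse`,
#'   `by`.
#' @return data.frame of class `"mr_estimate"` with one row per exposure
#'   (`mvmr_ivw:bx`, `mvmr_ivw:bx2`), Cochran's Q with df `k - p`.
#' @export
mr_mvivw <- function(set) {
  set <- .as_set(set)
  if (!"bx2" %in% names(set)) stop("multivariable IVW needs a `bx2` column")
  X <- cbind(bx = set$bx, bx2 = set$bx2)
  zero <- colSums(abs(X)) == 0
  if (any(zero)) {
    message("dropping all-zero exposure column(s): ",
            paste(colnames(X)[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  p <- ncol(X)
  k <- nrow(set)
  if (k < p + 1L) stop("multivariable IVW needs >= ", p + 1L, " SNPs")
  w <- 1 / set$byse^2
  XtWX <- crossprod(X * sqrt(w))
  if (qr(XtWX)$rank < p) stop("rank-deficient exposure design")
  XtWy <- crossprod(X, w * set$by)
  beta <- solve(XtWX, XtWy)[, 1L]
  resid <- set$by - X %*% beta
  q <- sum(w * resid^2)
  q_df <- k - p
  phi <- max(1, q / q_df)
  se <- sqrt(phi * diag(solve(XtWX)))
  out <- do.call(rbind, lapply(seq_len(p), function(j) {
    mr_estimate(beta[j], se[j], method = paste0("mvmr_ivw:", colnames(X)[j]),
                k_snps = k, cochran_q = q, q_df = q_df)
  }))
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' Instrument strength: variance explained and F statistics
#'
#' Per-SNP variance explained `r2_j = 2 eaf_j (1 - eaf_j) beta_j^2 /
#' trait_variance` and `F_j = r2_j (n_j - 2) / (1 - r2_j)`; for independent
#' instruments the total R^2 is the sum. These are the standard relevance
#' diagnostics reported alongside MR results.
#'
#' @param records data.frame of summary statistics with columns `EAF`,
#'   `BETA`, `N`.
#' @param trait_variance phenotypic variance of the exposure on the scale of
#'   `BETA` (e.g. `sd^2` of age at menarche in years).
#' @return list of class `"instrument_strength"`: `r2_total`, `mean_f`, and
#'   per-SNP vectors `r2` and `f`.
#' @export
instrument_strength <- function(records, trait_variance) {
  if (!is.numeric(trait_variance) || trait_variance <= 0)
    stop("`trait_variance` must be positive")
  need <- c("EAF", "BETA", "N")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  r2 <- 2 * records$EAF * (1 - records$EAF) * records$BETA^2 / trait_variance
  f <- r2 * (records$N - 2) / (1 - r2)
  structure(list(r2_total = sum(r2), mean_f = mean(f), r2 = r2, f = f),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instruments: total R2 = %.4f (%.2f%%), mean F = %.1f (k = %d)\n",
              x$r2_total, 100 * x$r2_total, x$mean_f, length(x$f)))
  invisible(x)
}

#' IVW on a negative-control outcome
#'
#' Identical machinery to [mr_ivw()] applied to an outcome that cannot be
#' affected by the exposure (e.g. skin colour / tanning ability). Evidence of
#' association flags residual population stratification in the exposure GWAS.
#'
#' @inheritParams mr_ivw
#' @param alpha flagging threshold for the IVW p-value, default 0.05.
#' @return an `"mr_estimate"` row with extra column
#'   `stratification_flag` (logical).
#' @export
negative_control_outcome_mr <- function(set, alpha = 0.05,
                                        mode = c("multiplicative_random",
                                                 "fixed")) {
  est <- mr_ivw(set, mode = match.arg(mode))
  est$stratification_flag <- est$p < alpha
  est
}
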