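# Shared constructors for estimate rows returned across the package.

#' Construct an effect-estimate row
#'
#' One row per estimate, in SD units of the outcome per unit of the exposure,
#' with normal-theory 95% confidence limits (`beta +/- 1.96 se`).
#'
#' @param beta point estimate.
#' @param se standard error.
#' @param n analysed sample size.
#' @param method method label (e.g. `"ols"`, `"2sls"`, `"pgs_ratio"`).
#' @param model adjustment-model label (`"model1"`, `"model2"`, `"model3"`)
#'   or `NA` where not applicable.
#' @param p two-sided p-value; computed from the normal approximation when
#'   omitted.
#' @return data.frame of class `"effect_estimate"` with columns `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, `n`, `method`, `model`.
#' @export
effect_estimate <- function(beta, se, n, method, model = NA_character_,
                            p = NULL) {
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  out <- data.frame(
    beta = beta, se = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    p = p, n = as.integer(n),
    method = method, model = model,
    stringsAsFactors = FALSE
  )
  class(out) <- c("effect_estimate", "data.frame")
  out
}

# Internal: estimate row for summary-data MR methods.
mr_estimate <- function(beta, se, method, k_snps, cochran_q = NA_real_,
                        q_df = NA_integer_, p = NULL) {
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  out <- data.frame(
    beta = beta, se = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    p = p, method = method, k_snps = as.integer(k_snps),
    cochran_q = cochran_q, q_df = as.integer(q_df),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_estimate", "data.frame")
  out
}
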