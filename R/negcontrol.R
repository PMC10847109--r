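# Male negative-control arm: number of children in men shares the
# confounding structure of parity in women but cannot carry the causal
# mechanism, so concordant male/female associations point to bias.

#' Male negative-control comparison for parity
#'
#' Fits [fit_adjusted_model()] for `n_children` against each metabolite
#' separately in females and males, then classifies each pair:
#'
#' * `causal-suggestive` - the female association passes `alpha` while the
#'   male one does not (or points the opposite way): the pattern expected of
#'   a true effect of parity;
#' * `bias-suggestive` - estimates are directionally consistent with
#'   overlapping 95% CIs: the pattern expected of shared confounding;
#' * `inconclusive` - anything else.
#'
#' The causal check takes precedence (a strongly confounded pair where the
#' female estimate also carries a causal component can satisfy both
#' descriptions; the male-null condition is the discriminating one). A
#' z-test of the female-male difference is reported so users can apply their
#' own concordance rule.
#'
#' @param cohort cohort data.frame containing both sexes and `n_children`.
#' @param metabolites character vector of outcome columns.
#' @param model adjustment model label, as in [fit_adjusted_model()].
#' @param alpha significance threshold for the causal check; defaults to the
#'   pipeline's Bonferroni threshold `0.05/54`.
#' @return data.frame of class `"negcontrol_verdicts"`, one row per
#'   metabolite: female and male estimates, `same_direction`, `ci_overlap`,
#'   `z_diff`, `p_diff`, `classification`.
#' @export
run_negative_control <- function(cohort, metabolites,
                                 model = c("model2", "model1", "model3"),
                                 alpha = bonferroni_threshold(3, 18)) {
  model <- match.arg(model)
  sexes <- unique(cohort$sex)
  if (!all(c("female", "male") %in% sexes))
    stop("negative control needs both sexes in the cohort")
  fem <- cohort[cohort$sex == "female", , drop = FALSE]
  mal <- cohort[cohort$sex == "male", , drop = FALSE]
  rows <- lapply(metabolites, function(m) {
    ef <- fit_adjusted_model(fem, "parity", m, model)
    em <- fit_adjusted_model(mal, "parity", m, model)
    same_dir <- sign(ef$beta) == sign(em$beta)
    overlap <- ef$ci_low <= em$ci_high & em$ci_low <= ef$ci_high
    z <- (ef$beta - em$beta) / sqrt(ef$se^2 + em$se^2)
    female_sig <- ef$p < alpha
    male_null <- em$p >= alpha
    cls <- if (female_sig && (male_null || !same_dir)) "causal-suggestive"
    else if (same_dir && overlap) "bias-suggestive"
    else "inconclusive"
    data.frame(
      metabolite = m,
      beta_f = ef$beta, se_f = ef$se, p_f = ef$p, n_f = ef$n,
      beta_m = em$beta, se_m = em$se, p_m = em$p, n_m = em$n,
      same_direction = same_dir, ci_overlap = overlap,
      z_diff = z, p_diff = 2 * stats::pnorm(-abs(z)),
      classification = cls, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  attr(out, "alpha") <- alpha
  class(out) <- c("negcontrol_verdicts", "data.frame")
  out
}
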