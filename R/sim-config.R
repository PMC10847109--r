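# Simulation configuration: the generator's defaults are the study
# conditions the pipeline is designed for (sample sizes, instrument strength,
# panel structure, missingness and age patterning of the menopause effect).

#' Default metabolite column names
#'
#' The first columns carry named roles used by the default causal wiring
#' (LDL cholesterol, VLDL triglycerides, HDL cholesterol, glycoprotein
#' acetyls, glutamine, glycine, DHA); the remainder are anonymous panel
#' members.
#'
#' @param n panel width.
#' @return character vector of length `n`.
#' @export
metabolite_names <- function(n) {
  base <- c("LDL_C", "VLDL_TG", "HDL_C", "GlycA", "Glutamine", "Glycine",
            "DHA")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("met_%02d", seq.int(length(base) + 1L, n)))
}

#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles and validates every quantity the generator needs. Defaults encode
#' the emulated study: ~50k women and ~40k men; three genetic instrument sets
#' explaining 7.4% (menarche), 0.2% (parity) and 8.2% (menopause) of exposure
#' variance; a 36-column metabolite panel driven by 18 latent factors
#' carrying 95% of panel variance (so 18 principal components explain >= 95%);
#' confounding by socioeconomic position, childhood adiposity and adult BMI;
#' a bidirectional menarche-BMI structure (childhood adiposity raises BMI and
#' lowers menarche age; menarche age has a residual path into adult BMI);
#' menopause ages missing for premenopausal (24.5%), surgical (12.0%) and
#' "other" (4.4%) strata, with premenopausal status tied to younger baseline
#' age; and an age-modified menopause effect on LDL cholesterol
#' (-0.0068 SD/yr at the mean baseline age of 56.4, slope +0.00102 per year
#' of baseline age, so the effect is negative in women aged <=50 and slightly
#' positive above 63).
#'
#' @param n_females,n_males cohort sizes.
#' @param n_snps_per_exposure instruments simulated per exposure.
#' @param maf_range range of effect-allele frequencies, inside (0, 1).
#' @param instrument_r2 named fractions of exposure variance explained by
#'   each instrument set.
#' @param causal_effects named list (`menarche`, `parity`, `menopause`), each
#'   a named vector of direct effects (SD of metabolite per exposure unit).
#'   Metabolite names must exist in the panel.
#' @param confounder_effects nested list of confounder paths: `exposures`
#'   (per exposure, named effects of `ses` / `child_adiposity` latents),
#'   `bmi` (effects of `child_adiposity` and standardized `menarche` on BMI,
#'   SD units), and `metabolites` (per confounder, named metabolite effects;
#'   confounders `bmi`, `ses`, `child_adiposity`, `smoking`).
#' @param pleiotropy list `proportion_invalid`, `effect_sd`, `directional`:
#'   invalid instruments receive direct SNP-to-metabolite effects drawn
#'   `Normal(mu, effect_sd)` with `mu = effect_sd` when `directional` else 0.
#' @param adiposity_genetics fraction of the childhood-adiposity latent's
#'   variance driven by the menarche instrument SNPs (females). This shared
#'   genetic path makes menarche instruments act on adult BMI both through
#'   menarche and through childhood adiposity, the structure multivariable
#'   MR conditions away; direct menarche SNP effects are rescaled so the
#'   total instrument R^2 stays at `instrument_r2["menarche"]`.
#' @param n_metabolites,n_factors panel width and number of latent factors.
#' @param factor_share fraction of metabolite variance carried by the latent
#'   factors (calibrates the effective-test count).
#' @param menopause_missing list of `premenopausal_frac`, `surgical_frac`,
#'   `other_frac`.
#' @param age_modification named vector: per-year-of-baseline-age slope of
#'   the menopause effect for the named metabolites.
#' @param stratification list `effect` (shift of allele frequencies per SD of
#'   an ancestry latent; 0 disables) and `outcome_loading` (loading of that
#'   latent on the negative-control outcome columns).
#' @param exposure_dist named list of distribution parameters (`mean`, `sd`,
#'   and for `age` also `min`, `max`) for `menarche`, `parity`, `menopause`,
#'   `age`, `bmi`.
#' @param seed integer; the same seed gives bit-identical output.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(
    n_females = 50000L,
    n_males = 40000L,
    n_snps_per_exposure = 100L,
    maf_range = c(0.05, 0.5),
    instrument_r2 = c(menarche = 0.074, parity = 0.002, menopause = 0.082),
    causal_effects = list(
      menarche = c(Glutamine = 0.02, Glycine = 0.015),
      parity = c(VLDL_TG = 0.03, HDL_C = -0.02, DHA = -0.02),
      menopause = c(LDL_C = -0.0068, GlycA = -0.005)
    ),
    confounder_effects = list(
      exposures = list(
        menarche = c(child_adiposity = -0.35, ses = 0.10),
        parity = c(ses = -0.25, child_adiposity = 0.10),
        menopause = c(ses = 0.30)
      ),
      bmi = c(child_adiposity = 0.45, menarche = -0.16),
      metabolites = list(
        bmi = c(LDL_C = 0.15, VLDL_TG = 0.25, HDL_C = -0.20, GlycA = 0.15,
                met_08 = 0.10, met_09 = 0.10, met_10 = 0.10),
        ses = c(LDL_C = -0.04, HDL_C = 0.04, DHA = 0.05, met_11 = -0.05),
        child_adiposity = c(VLDL_TG = 0.05, met_12 = 0.05),
        smoking = c(GlycA = 0.10)
      )
    ),
    pleiotropy = list(proportion_invalid = 0, effect_sd = 0,
                      directional = FALSE),
    adiposity_genetics = 0.15,
    n_metabolites = 36L,
    n_factors = 18L,
    factor_share = 0.95,
    menopause_missing = list(premenopausal_frac = 0.245,
                             surgical_frac = 0.120,
                             other_frac = 0.044),
    age_modification = c(LDL_C = 0.00102),
    stratification = list(effect = 0, outcome_loading = 1),
    exposure_dist = list(
      menarche = c(mean = 13.0, sd = 1.6),
      parity = c(mean = 1.8, sd = 1.2),
      menopause = c(mean = 49.7, sd = 5.1),
      age = c(mean = 56.4, sd = 8.0, min = 38, max = 73),
      bmi = c(mean = 27.1, sd = 5.2)
    ),
    seed = 1L) {
  cfg <- list(
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    n_snps_per_exposure = as.integer(n_snps_per_exposure),
    maf_range = maf_range, instrument_r2 = instrument_r2,
    causal_effects = causal_effects, confounder_effects = confounder_effects,
    pleiotropy = pleiotropy, adiposity_genetics = adiposity_genetics,
    n_metabolites = as.integer(n_metabolites),
    n_factors = as.integer(n_factors), factor_share = factor_share,
    menopause_missing = menopause_missing,
    age_modification = age_modification, stratification = stratification,
    exposure_dist = exposure_dist, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a candidate configuration list.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (n_females < 1L || n_snps_per_exposure < 1L)
      stop("configuration error: counts must be positive")
    if (n_males < 0L)
      stop("configuration error: n_males must be non-negative")
    if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range >= 1) ||
        maf_range[1] > maf_range[2])
      stop("configuration error: maf_range must be an increasing pair in (0, 1)")
    if (n_factors > n_metabolites)
      stop("configuration error: n_factors must not exceed n_metabolites")
    if (factor_share <= 0 || factor_share >= 1)
      stop("configuration error: factor_share must be in (0, 1)")
    fr <- unlist(menopause_missing)
    if (any(fr < 0) || any(fr > 1))
      stop("configuration error: missingness fractions must be in [0, 1]")
    if (menopause_missing$premenopausal_frac +
        menopause_missing$surgical_frac >= 1)
      stop("configuration error: premenopausal_frac + surgical_frac must be < 1")
    pv <- pleiotropy$proportion_invalid
    if (pv < 0 || pv > 1)
      stop("configuration error: proportion_invalid must be in [0, 1]")
    if (adiposity_genetics < 0 || adiposity_genetics >= 1)
      stop("configuration error: adiposity_genetics must be in [0, 1)")
    mets <- metabolite_names(n_metabolites)
    for (ex in names(causal_effects)) {
      bad <- setdiff(names(causal_effects[[ex]]), mets)
      if (length(bad))
        stop("configuration error: causal_effects$", ex,
             " names unknown metabolite(s): ", paste(bad, collapse = ", "))
    }
    bad <- setdiff(names(age_modification), mets)
    if (length(bad))
      stop("configuration error: age_modification names unknown metabolite(s): ",
           paste(bad, collapse = ", "))
  })
  structure(config, class = c("sim_config", "list"))
}

# Internal: expand a named effect vector onto the full metabolite name set.
.expand_effects <- function(effects, met_names) {
  out <- stats::setNames(numeric(length(met_names)), met_names)
  if (length(effects)) out[names(effects)] <- effects
  out
}

#' Zero out every causal and confounding path of a configuration
#'
#' Used for null calibration: exposures and metabolites become mutually
#' independent apart from the shared factor structure of the panel.
#'
#' @param config a [sim_config()] object.
#' @return modified configuration.
#' @export
null_config <- function(config) {
  zero <- function(v) {v[] <- 0; v}
  config$causal_effects <- lapply(config$causal_effects, zero)
  config$confounder_effects$exposures <-
    lapply(config$confounder_effects$exposures, zero)
  config$confounder_effects$bmi <- zero(config$confounder_effects$bmi)
  config$confounder_effects$metabolites <-
    lapply(config$confounder_effects$metabolites, zero)
  config$age_modification <- zero(config$age_modification)
  validate_sim_config(config)
}
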