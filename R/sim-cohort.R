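# Individual-level cohort simulation with the causal and confounding
# structure the triangulation design assumes: genetically instrumented
# exposures, shared female/male confounding of the parity path, a
# bidirectional menarche-BMI structure, factor-correlated metabolites,
# age-linked menopause missingness, and an age-modified menopause effect.

# Internal: residual SD topping a deterministic component up to a target
# variance (floored so degenerate configurations keep some noise).
.resid_sd <- function(target_var, deterministic) {
  sqrt(max(target_var - stats::var(deterministic), 0.02 * target_var))
}

# Internal: cut a latent at its sample quantiles into labelled categories
# with the supplied proportions.
.cut_latent <- function(latent, probs, labels) {
  qs <- stats::quantile(latent, cumsum(probs)[-length(probs)], names = FALSE)
  cut(latent, breaks = c(-Inf, qs, Inf), labels = labels, right = TRUE)
}

#' Simulate an individual-level cohort
#'
#' Generates females and males under the configured causal structure:
#'
#' * latent socioeconomic position (`ses`) and childhood adiposity
#'   (`child_adiposity`) drive education, body size at age 10, adult BMI,
#'   all three reproductive exposures and (weakly) the metabolites - the
#'   confounding the regression models try to block;
#' * each exposure has an additive genetic score (independent HWE SNPs)
#'   explaining its configured variance fraction;
#' * adult BMI receives childhood adiposity plus a residual path from age at
#'   menarche, and feeds the metabolite panel - so menarche effects on
#'   lipids are BMI-mediated and attenuate under BMI adjustment;
#' * metabolites share 18 latent factors carrying `factor_share` of their
#'   variance, giving the correlated panel whose effective test count is 18;
#' * males get `n_children` from the same confounders with no causal path to
#'   any metabolite (the negative-control arm), and no reproductive columns;
#' * menopause age is observed only for the natural-menopause stratum;
#'   premenopausal assignment ranks on latent menopause age minus baseline
#'   age (plus noise), so the selected sample skews old;
#' * the menopause effect on metabolites named in `age_modification` varies
#'   linearly with baseline age.
#'
#' @param config a [sim_config()] object; `config$seed` makes the output
#'   bit-identical across calls.
#' @return list of class `"cohort_sim"`:
#' \describe{
#'   \item{cohort}{data.frame, one row per individual (females first):
#'     `id`, `sex`, `age_baseline`, `education`, `body_size_age10`, `bmi`,
#'     `smoking`, `alcohol`, `menarche_age`, `n_children`, `menopause_age`
#'     (observed; `NA` unless natural menopause), `menopause_status`,
#'     `menopause_latent` (generator ground truth), `statin_flag`,
#'     `hrt_flag`, `skin_tone`, `tanning`, and one column per metabolite.}
#'   \item{genotypes}{named list of three integer matrices (female rows
#'     only), one per exposure, with allele/MAF attributes as in
#'     [simulate_genotypes()]. Kept alongside rather than inside the cohort
#'     table: males never use them and the matrices are large.}
#'   \item{snps}{named list of data.frames `snp`, `ea`, `oa`, `maf`,
#'     `beta` (true per-allele exposure effects).}
#'   \item{config}{the configuration used.}
#' }
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  nf <- config$n_females
  nm <- config$n_males
  n <- nf + nm
  dist <- config$exposure_dist
  mets <- metabolite_names(config$n_metabolites)
  ce <- config$confounder_effects

  ## shared latents ---------------------------------------------------------
  ses <- stats::rnorm(n)
  child <- stats::rnorm(n)
  ancestry <- stats::rnorm(n)
  age <- pmin(pmax(stats::rnorm(n, dist$age["mean"], dist$age["sd"]),
                   dist$age["min"]), dist$age["max"])
  female <- seq_len(n) <= nf

  education <- .cut_latent(ses + stats::rnorm(n, 0, 0.6),
                           c(0.169, 0.394, 0.117, 0.320),
                           c("none", "olevel", "alevel", "university"))
  education <- factor(as.character(education),
                      levels = c("none", "olevel", "alevel", "university"))
  smoking <-.cut_latent(-0.3 * ses + stats::rnorm(n),
                         c(0.595, 0.315, 0.090),
                         c("never", "previous", "current"))
  alcohol <- .cut_latent(0.2 * ses + stats::rnorm(n),
                         c(0.160, 0.209, 0.257, 0.132, 0.147, 0.094),
                         c("daily", "wk3_4", "wk1_2", "mo1_3",
                           "special", "never"))

  ## genetic instruments (females carry the genotype matrices) --------------
  exposures <- c("menarche", "parity", "menopause")
  strat_eff <- config$stratification$effect
  genotypes <- list()
  snps <- list()
  gscore <- matrix(0, nf, length(exposures),
                   dimnames = list(NULL, exposures))
  var_targets <- c(menarche = unname(dist$menarche["sd"])^2,
                   parity = unname(dist$parity["sd"])^2,
                   menopause = unname(dist$menopause["sd"])^2)
  k <- config$n_snps_per_exposure
  vshare <- config$adiposity_genetics
  child_eff <- config$confounder_effects$exposures$menarche[["child_adiposity"]]
  for (ex in exposures) {
    mafs <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    g <- .draw_genotypes(nf, mafs, strat = ancestry[female],
                         strat_effect = strat_eff)
    al <- .draw_alleles(k)
    ids <- sprintf("%s_rs_%04d", substr(ex, 1, 4), seq_len(k))
    colnames(g) <- ids
    attr(g, "ea") <- al$ea; attr(g, "oa") <- al$oa; attr(g, "maf") <- mafs
    r2_ex <- config$instrument_r2[[ex]]
    if (ex == "menarche" && vshare > 0) {
      # part of the menarche instruments' R^2 flows through childhood
      # adiposity; keep the total at the configured value
      gvar_direct <- max(r2_ex * var_targets[[ex]] -
                           child_eff^2 * vshare,
                         0.2 * r2_ex * var_targets[[ex]])
      r2_ex <- gvar_direct / var_targets[[ex]]
      delta <- abs(stats::rnorm(k)) + 0.2
      delta <- delta * sqrt(vshare / sum(2 * mafs * (1 - mafs) * delta^2))
      gad <- as.numeric(g %*% delta)
      child[female] <- sqrt(1 - vshare) * child[female] + gad - mean(gad)
    }
    beta <- .instrument_effects(r2_ex, var_targets[[ex]], mafs)
    genotypes[[ex]] <- g
    snps[[ex]] <- data.frame(snp = ids, ea = al$ea, oa = al$oa, maf = mafs,
                             beta = beta, stringsAsFactors = FALSE)
    sc <- as.numeric(g %*% beta)
    gscore[, ex] <- sc - mean(sc)
  }

  ## childhood body size reported from the (partly genetic) adiposity latent
  body_size <- .cut_latent(child, c(0.316, 0.507, 0.177),
                           c("thinner", "average", "plumper"))

  ## exposures (females) ----------------------------------------------------
  exf <- ce$exposures
  confpart <- function(ex) {
    eff <- exf[[ex]]
    out <- numeric(nf)
    if ("ses" %in% names(eff))
      out <- out + eff[["ses"]] * ses[female]
    if ("child_adiposity" %in% names(eff))
      out <- out + eff[["child_adiposity"]] * child[female]
    out
  }
  men_det <- gscore[, "menarche"] + confpart("menarche")
  menarche <- dist$menarche["mean"] + men_det +
    stats::rnorm(nf, 0, .resid_sd(var_targets["menarche"], men_det))

  par_det <- gscore[, "parity"] + confpart("parity")
  parity_latent_f <- dist$parity["mean"] + par_det +
    stats::rnorm(nf, 0, .resid_sd(var_targets["parity"], par_det))

  meno_det <- gscore[, "menopause"] + confpart("menopause")
  menopause <- dist$menopause["mean"] + meno_det +
    stats::rnorm(nf, 0, .resid_sd(var_targets["menopause"], meno_det))

  ## adult BMI: childhood adiposity for everyone, menarche residual path
  ## for females only
  bmi_cfg <- ce$bmi
  menarche_z <- (menarche - dist$menarche["mean"]) / dist$menarche["sd"]
  bmi_det <- bmi_cfg[["child_adiposity"]] * child
  bmi_det[female] <- bmi_det[female] + bmi_cfg[["menarche"]] * menarche_z
  bmi_z <- bmi_det + stats::rnorm(n, 0, .resid_sd(1, bmi_det))
  bmi <- dist$bmi["mean"] + dist$bmi["sd"] * bmi_z

  ## parity for males: same confounders, no causal path downstream
  par_det_m <- numeric(nm)
  effp <- exf$parity
  if ("ses" %in% names(effp)) par_det_m <- par_det_m + effp[["ses"]] * ses[!female]
  if ("child_adiposity" %in% names(effp))
    par_det_m <- par_det_m + effp[["child_adiposity"]] * child[!female]
  parity_latent_m <- dist$parity["mean"] + par_det_m +
    stats::rnorm(nm, 0, .resid_sd(var_targets["parity"], par_det_m))
  n_children <- pmin(pmax(round(c(parity_latent_f, parity_latent_m)), 0L), 12L)

  ## menopause status and observed age --------------------------------------
  mm <- config$menopause_missing
  pre_score <- (menopause - age[female]) + stats::rnorm(nf, 0, 3)
  status <- rep("natural", nf)
  n_pre <- round(mm$premenopausal_frac * nf)
  if (n_pre > 0)
    status[order(pre_score, decreasing = TRUE)[seq_len(n_pre)]] <- "pre"
  rest <- which(status == "natural")
  denom <- max(1 - mm$premenopausal_frac, 1e-9)
  u <- stats::runif(length(rest))
  status[rest[u < mm$surgical_frac / denom]] <- "surgical"
  u2 <- stats::runif(length(rest))
  still <- status[rest] == "natural"
  status[rest[still & u2 < mm$other_frac / (denom - mm$surgical_frac)]] <- "other"
  menopause_obs <- ifelse(status == "natural", menopause, NA_real_)

  ## medication flags (age-patterned prevalence) ----------------------------
  statin <- stats::rbinom(n, 1L,
                          stats::plogis(stats::qlogis(0.113) +
                                          0.04 * (age - 56.4))) == 1L
  hrt <- female & stats::rbinom(n, 1L,
                                stats::plogis(stats::qlogis(0.383) +
                                                0.02 * (age - 56.4))) == 1L

  ## metabolite panel -------------------------------------------------------
  kf <- config$n_factors
  loading <- sqrt(config$factor_share)
  eps_sd <- sqrt(1 - config$factor_share)
  assign_f <- ((seq_len(config$n_metabolites) - 1L) %% kf) + 1L
  fac <- matrix(stats::rnorm(n * kf), n, kf)
  Y <- fac[, assign_f, drop = FALSE] * loading +
    matrix(stats::rnorm(n * config$n_metabolites, 0, eps_sd), n)
  colnames(Y) <- mets

  me <- ce$metabolites
  Y <- Y + outer(bmi_z, .expand_effects(me$bmi, mets))
  Y <- Y + outer(ses, .expand_effects(me$ses, mets))
  Y <- Y + outer(child, .expand_effects(me$child_adiposity, mets))
  Y <- Y + outer(as.numeric(smoking == "current"),
                 .expand_effects(me$smoking, mets))

  ## causal paths, females only
  men_c <- menarche - dist$menarche["mean"]
  par_c <- n_children[female] - mean(n_children[female])
  meno_c <- menopause - dist$menopause["mean"]
  agef_c <- age[female] - 56.4
  add_causal <- function(Y, centred, effects, modify = NULL) {
    for (m in names(effects)) {
      eff <- effects[[m]]
      if (!is.null(modify) && m %in% names(modify))
        eff <- eff + modify[[m]] * agef_c
      Y[female, m] <- Y[female, m] + centred * eff
    }
    Y
  }
  Y <- add_causal(Y, men_c, as.list(config$causal_effects$menarche))
  Y <- add_causal(Y, par_c, as.list(config$causal_effects$parity))
  Y <- add_causal(Y, meno_c, as.list(config$causal_effects$menopause),
                  modify = as.list(config$age_modification))

  ## pleiotropy: invalid instruments act on the panel directly
  pl <- config$pleiotropy
  if (pl$proportion_invalid > 0 && pl$effect_sd > 0) {
    mu <- if (isTRUE(pl$directional)) pl$effect_sd else 0
    for (ex in exposures) {
      n_inv <- round(pl$proportion_invalid * k)
      if (n_inv < 1L) next
      j <- sample.int(k, n_inv)
      alpha <- matrix(stats::rnorm(n_inv * config$n_metabolites, mu,
                                   pl$effect_sd),
                      n_inv, config$n_metabolites)
      Y[female, ] <- Y[female, ] + genotypes[[ex]][, j, drop = FALSE] %*% alpha
    }
  }

  ## negative-control outcomes (ancestry-loaded when stratification is on)
  load_nc <- if (strat_eff != 0) config$stratification$outcome_loading else 0
  skin_tone <- load_nc * ancestry + stats::rnorm(n)
  tanning <- load_nc * ancestry + stats::rnorm(n)

  cohort <- data.frame(
    id = sprintf("id_%06d", seq_len(n)),
    sex = ifelse(female, "female", "male"),
    age_baseline = age,
    education = education,
    body_size_age10 = body_size,
    bmi = bmi,
    smoking = smoking,
    alcohol = alcohol,
    menarche_age = c(menarche, rep(NA_real_, nm)),
    n_children = n_children,
    menopause_age = c(menopause_obs, rep(NA_real_, nm)),
    menopause_status = c(status, rep(NA_character_, nm)),
    menopause_latent = c(menopause, rep(NA_real_, nm)),
    statin_flag = statin,
    hrt_flag = hrt,
    skin_tone = skin_tone,
    tanning = tanning,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(Y))

  structure(list(cohort = cohort, genotypes = genotypes, snps = snps,
                 config = config, metabolites = mets),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d females + %d males, %d metabolites, %d SNPs/exposure\n",
    x$config$n_females, x$config$n_males, x$config$n_metabolites,
    x$config$n_snps_per_exposure))
  invisible(x)
}
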