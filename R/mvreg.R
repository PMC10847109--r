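# Multivariable regression arm: the three adjustment models, exposure
# categorisation, likelihood-ratio non-linearity tests, medication-exclusion
# filters and chronological-age stratification.

.exposure_col <- function(cohort, exposure) {
  map <- c(menarche = "menarche_age", parity = "n_children",
           menopause = "menopause_age")
  col <- if (exposure %in% names(map)) map[[exposure]] else exposure
  if (!col %in% names(cohort))
    stop("exposure column `", col, "` not found in cohort")
  col
}

.model_covariates <- function(model) {
  switch(model,
         model1 = character(0),
         model2 = c("education", "age_baseline", "body_size_age10"),
         model3 = c("education", "age_baseline", "body_size_age10",
                    "bmi", "smoking", "alcohol"),
         stop("`model` must be one of model1, model2, model3"))
}

# Internal: complete-case analysis frame for one exposure-outcome-model
# triple. Categorical covariates stay factors and enter as indicator
# contrasts in the model matrix.
.analysis_frame <- function(cohort, exposure_col, outcome, model) {
  covars <- .model_covariates(model)
  miss <- setdiff(c(exposure_col, outcome, covars), names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  d <- cohort[, c(exposure_col, outcome, covars), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  list(data = d, covars = covars)
}

#' Fit one adjustment model for an exposure-metabolite pair
#'
#' Ordinary least squares of the outcome on the continuous exposure, under
#' one of the three covariate sets: `model1` unadjusted; `model2` adjusted
#' for education, age at baseline and body size at age 10 (the primary
#' causal model); `model3` additionally adjusted for baseline BMI, smoking
#' and alcohol (covariates that may be mediators). Complete-case per triple;
#' 95% CIs use the normal multiplier 1.96.
#'
#' @param cohort cohort data.frame (see [simulate_cohort()]).
#' @param exposure `"menarche"`, `"parity"`, `"menopause"` or a column name.
#' @param outcome outcome column name (typically a transformed metabolite).
#' @param model `"model1"`, `"model2"` or `"model3"`.
#' @return an [effect_estimate()] row, `method = "ols"`.
#' @export
fit_adjusted_model <- function(cohort, exposure, outcome,
                               model = c("model2", "model1", "model3")) {
  model <- match.arg(model)
  xcol <- .exposure_col(cohort, exposure)
  af <- .analysis_frame(cohort, xcol, outcome, model)
  d <- af$data
  if (nrow(d) < 30L)
    stop("fewer than 30 complete cases for ", exposure, " / ", outcome)
  fml <- stats::reformulate(c(xcol, af$covars), response = outcome)
  fit <- stats::lm(fml, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("collinear covariates: ", paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  effect_estimate(beta = sm[xcol, 1L], se = sm[xcol, 2L], n = nrow(d),
                  method = "ols", model = model, p = sm[xcol, 4L])
}

#' Categorise a reproductive exposure
#'
#' Age at menarche into tertile bands `<13`, `13-14`, `>14` years; age at
#' menopause into quartile bands `<49`, `49-50`, `51-53`, `>53` years;
#' parity into `0`, `1`, `2`, `3+`.
#'
#' @param exposure `"menarche"`, `"parity"` or `"menopause"`.
#' @param values numeric vector.
#' @return factor with the exposure's category levels (`NA` preserved).
#' @export
categorize <- function(exposure, values) {
  switch(exposure,
    menarche = cut(values, breaks = c(-Inf, 13, 15, Inf), right = FALSE,
                   labels = c("<13", "13-14", ">14")),
    menopause = cut(values, breaks = c(-Inf, 49, 51, 54, Inf), right = FALSE,
                    labels = c("<49", "49-50", "51-53", ">53")),
    parity = {
      if (any(values < 0, na.rm = TRUE)) stop("negative parity")
      cut(values, breaks = c(-Inf, 0.5, 1.5, 2.5, Inf),
          labels = c("0", "1", "2", "3+"))
    },
    stop("`exposure` must be menarche, parity or menopause")
  )
}

#' Likelihood-ratio test of non-linearity across exposure categories
#'
#' Compares the categorised exposure entered as indicator contrasts against a
#' single linear-in-category-scores term (integer scores 1..k; the choice of
#' scores is recorded in the output), both with the chosen model's
#' covariates. The LRT uses Gaussian likelihoods from the OLS fits with
#' `df = k - 2`; the trend p-value comes from the score-linear model.
#' Categories with fewer than 2 rows are dropped with a warning.
#'
#' @inheritParams fit_adjusted_model
#' @return list with `lrt_stat`, `df`, `p_trend`, `p_nonlinear`, `n`,
#'   `categories` (occupied levels) and `scores`.
#' @export
test_nonlinearity <- function(cohort, exposure, outcome,
                              model = c("model2", "model1", "model3")) {
  model <- match.arg(model)
  xcol <- .exposure_col(cohort, exposure)
  af <- .analysis_frame(cohort, xcol, outcome, model)
  d <- af$data
  cat_all <- categorize(exposure, d[[xcol]])
  counts <- table(cat_all)
  small <- names(counts)[counts < 2L & counts > 0L]
  if (length(small)) {
    warning("dropping category(ies) with < 2 rows: ",
            paste(small, collapse = ", "))
    keep <- !(as.character(cat_all) %in% small)
    d <- d[keep, , drop = FALSE]
    cat_all <- droplevels(cat_all[keep])
  } else {
    cat_all <- droplevels(cat_all)
  }
  k <- nlevels(cat_all)
  if (k < 3L)
    stop("non-linearity test needs >= 3 occupied categories (found ", k, ")")
  d$.category <- cat_all
  d$.score <- as.integer(cat_all)
  f_cat <- stats::lm(stats::reformulate(c(".category", af$covars),
                                        response = outcome), data = d)
  f_lin <- stats::lm(stats::reformulate(c(".score", af$covars),
                                        response = outcome), data = d)
  lrt <- as.numeric(2 * (stats::logLik(f_cat) - stats::logLik(f_lin)))
  df <- k - 2L
  sm <- summary(f_lin)$coefficients
  list(
    lrt_stat = lrt, df = df,
    p_trend = sm[".score", 4L],
    p_nonlinear = stats::pchisq(lrt, df, lower.tail = FALSE),
    n = nrow(d), categories = levels(cat_all),
    scores = seq_len(k)
  )
}

#' Drop users of statins and/or hormone replacement therapy
#'
#' @param cohort cohort data.frame with logical `statin_flag` / `hrt_flag`.
#' @param which `"statin"`, `"hrt"` or `"both"`.
#' @return filtered cohort; removed counts are reported via `message()` and
#'   kept in attribute `n_excluded`.
#' @export
exclude_medication <- function(cohort, which = c("statin", "hrt", "both")) {
  which <- match.arg(which)
  flags <- switch(which,
                  statin = cohort$statin_flag,
                  hrt = cohort$hrt_flag,
                  both = cohort$statin_flag | cohort$hrt_flag)
  if (is.null(flags)) stop("medication flag column(s) missing")
  drop <- !is.na(flags) & flags
  message("excluding ", sum(drop), " of ", nrow(cohort), " rows (", which, ")")
  out <- cohort[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Stratify a cohort by chronological age at baseline
#'
#' Four strata: `<=50`, `(50, 58]`, `(58, 63]`, `>63` years. Rows with
#' missing age are excluded with a warning; the strata partition the
#' remaining rows.
#'
#' @param cohort cohort data.frame with `age_baseline`.
#' @return named list of four cohort data.frames
#'   (`age_le50`, `age_50_58`, `age_58_63`, `age_gt63`).
#' @export
age_stratify <- function(cohort) {
  age <- cohort$age_baseline
  if (is.null(age)) stop("cohort lacks `age_baseline`")
  if (anyNA(age)) {
    warning("excluding ", sum(is.na(age)), " row(s) with missing age")
    cohort <- cohort[!is.na(age), , drop = FALSE]
    age <- cohort$age_baseline
  }
  idx <- findInterval(age, c(50, 58, 63), left.open = TRUE) + 1L
  out <- lapply(1:4, function(s) cohort[idx == s, , drop = FALSE])
  names(out) <- c("age_le50", "age_50_58", "age_58_63", "age_gt63")
  out
}
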