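# Restricted cubic splines: natural cubic regression splines in the
# truncated-power parameterisation, linear beyond the boundary knots, with
# Harrell's default percentile knot placement.

#' Harrell percentile knot positions
#'
#' 3 knots at the (10, 50, 90) percentiles, 4 at (5, 35, 65, 95),
#' 5 at (5, 27.5, 50, 72.5, 95).
#'
#' @param x numeric vector (non-missing values used).
#' @param n_knots 3, 4 or 5.
#' @return numeric vector of knot positions.
#' @export
harrell_knots <- function(x, n_knots) {
  pcts <- switch(as.character(n_knots),
                 "3" = c(10, 50, 90),
                 "4" = c(5, 35, 65, 95),
                 "5" = c(5, 27.5, 50, 72.5, 95),
                 stop("`n_knots` must be 3, 4 or 5"))
  stats::quantile(x, pcts / 100, na.rm = TRUE, names = FALSE)
}

#' Restricted cubic spline basis
#'
#' Truncated-power basis with `k` knots `t_1 < ... < t_k`: the linear term
#' plus `k - 2` non-linear terms
#' \deqn{s_j(x) = \big[(x - t_j)_+^3 - (x - t_{k-1})_+^3
#'   \tfrac{t_k - t_j}{t_k - t_{k-1}} + (x - t_k)_+^3
#'   \tfrac{t_{k-1} - t_j}{t_k - t_{k-1}}\big] / (t_k - t_1)^2,}
#' which constrains the fitted function to be linear beyond the boundary
#' knots and scales the non-linear columns to the order of `x`.
#'
#' @param x numeric vector.
#' @param knots increasing knot positions (at least 3, no duplicates).
#' @return matrix with columns `x`, `s1`, ..., `s(k-2)`.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(knots)
  k <- length(knots)
  if (k < 3L) stop("need at least 3 knots")
  if (anyDuplicated(knots)) stop("duplicate knots")
  tk <- knots[k]; tk1 <- knots[k - 1L]; t1 <- knots[1L]
  cube <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1L)
  B[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    B[, j + 1L] <- (cube(x - tj) -
                      cube(x - tk1) * (tk - tj) / (tk - tk1) +
                      cube(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
  }
  colnames(B) <- c("x", paste0("s", seq_len(k - 2L)))
  B
}

#' Fit a restricted cubic spline model and its linear comparator
#'
#' Fits the outcome on the spline basis of the exposure plus the chosen
#' model's covariates, alongside the linear-in-exposure fit on the same
#' rows, and reports AIC, BIC and RMSE for both together with a
#' likelihood-ratio p-value for the non-linear terms.
#'
#' @inheritParams fit_adjusted_model
#' @param n_knots 3, 4 or 5.
#' @param knots optional explicit knot positions (otherwise Harrell
#'   percentiles of the analysed exposure values).
#' @return list of class `"spline_fit"`: `knots`, `n_knots`,
#'   `coefficients`, `aic`, `bic`, `rmse`, `p_nonlinear`, `n`,
#'   `linear` (list `aic`, `bic`, `rmse`, `beta`), `prefers_linear`
#'   (AIC comparison) and `fit` (the `lm` object).
#' @export
fit_rcs <- function(cohort, exposure, outcome, n_knots = 3, knots = NULL,
                    model = c("model2", "model1", "model3")) {
  model <- match.arg(model)
  if (!n_knots %in% 3:5) stop("`n_knots` must be 3, 4 or 5")
  xcol <- .exposure_col(cohort, exposure)
  af <- .analysis_frame(cohort, xcol, outcome, model)
  d <- af$data
  x <- d[[xcol]]
  if (is.null(knots)) knots <- harrell_knots(x, n_knots)
  if (length(knots) != n_knots)
    stop("`knots` must have length `n_knots`")
  B <- rcs_basis(x, knots)
  d2 <- cbind(d, as.data.frame(B))
  rhs <- c(colnames(B), af$covars)
  f_rcs <- stats::lm(stats::reformulate(rhs, response = outcome), data = d2)
  f_lin <- stats::lm(stats::reformulate(c("x", af$covars),
                                        response = outcome), data = d2)
  rmse <- function(f) sqrt(mean(stats::resid(f)^2))
  lrt <- as.numeric(2 * (stats::logLik(f_rcs) - stats::logLik(f_lin)))
  p_nl <- stats::pchisq(max(lrt, 0), df = n_knots - 2L, lower.tail = FALSE)
  out <- list(
    knots = sort(knots), n_knots = as.integer(n_knots),
    coefficients = stats::coef(f_rcs),
    aic = stats::AIC(f_rcs), bic = stats::BIC(f_rcs), rmse = rmse(f_rcs),
    p_nonlinear = p_nl, n = nrow(d2),
    linear = list(aic = stats::AIC(f_lin), bic = stats::BIC(f_lin),
                  rmse = rmse(f_lin), beta = stats::coef(f_lin)[["x"]]),
    prefers_linear = stats::AIC(f_lin) <= stats::AIC(f_rcs),
    fit = f_rcs
  )
  class(out) <- "spline_fit"
  out
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf(
    "Restricted cubic spline (%d knots at %s): AIC %.1f vs linear %.1f; p_nonlinear = %.3g\n",
    x$n_knots, paste(signif(x$knots, 4), collapse = ", "),
    x$aic, x$linear$aic, x$p_nonlinear))
  invisible(x)
}
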