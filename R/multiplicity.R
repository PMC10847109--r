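#' Effective number of independent tests in a correlated panel
#'
#' Principal component analysis of the panel correlation matrix: the effective
#' number of tests is the smallest number of components whose eigenvalues sum
#' to at least `threshold` of the total variance. For a standardized,
#' highly correlated metabolite panel this is far below the column count and
#' is the denominator used for Bonferroni correction.
#'
#' @param panel numeric matrix or data.frame (rows = individuals,
#'   columns = measures).
#' @param threshold fraction of variance to capture, default 0.95.
#' @param use `"complete"` (default; correlation from complete rows) or
#'   `"pairwise"`. Pairwise-complete correlation matrices need not be positive
#'   semi-definite; negative eigenvalues trigger a warning.
#' @return integer count, with the eigenvalue spectrum in attribute
#'   `eigenvalues`.
#' @seealso [bonferroni_threshold()], [multiplicity_correction()]
#' @export
effective_tests <- function(panel, threshold = 0.95, use = c("complete", "pairwise")) {
  use <- match.arg(use)
  m <- as.matrix(panel)
  if (!is.numeric(m)) stop("`panel` must be numeric")
  if (ncol(m) < 2L) stop("`panel` needs at least 2 columns")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]")
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    bad <- colnames(m)[!is.finite(sds) | sds == 0]
    stop("constant or all-missing column(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
  }
  R <- stats::cor(m, use = if (use == "complete") "complete.obs" else
    "pairwise.complete.obs")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (use == "pairwise" && any(ev < -1e-8))
    warning("pairwise-complete correlation matrix has negative eigenvalues")
  cum <- cumsum(ev) / sum(ev)
  n_eff <- which(cum >= threshold - 1e-12)[1L]
  structure(as.integer(n_eff), eigenvalues = ev)
}

#' Bonferroni threshold for multiple exposures over an effective test count
#'
#' @param n_exposures number of exposures analysed (3 for menarche, parity and
#'   menopause).
#' @param n_eff effective number of independent outcome features (from
#'   [effective_tests()]).
#' @return two-sided p-value threshold `0.05 / (n_exposures * n_eff)`.
#' @examples
#' bonferroni_threshold(3, 18)  # 0.05 / 54
#' @export
bonferroni_threshold <- function(n_exposures, n_eff) {
  if (!is.numeric(n_exposures) || !is.numeric(n_eff) ||
      n_exposures < 1 || n_eff < 1)
    stop("`n_exposures` and `n_eff` must be positive counts")
  0.05 / (as.numeric(n_exposures) * as.numeric(n_eff))
}

#' Full multiplicity correction for a metabolite panel
#'
#' Convenience wrapper combining [effective_tests()] and
#' [bonferroni_threshold()]. The panel is rank-inverse-normal transformed
#' first (correlation PCA of the standardized panel) unless `transform = FALSE`.
#'
#' @param panel metabolite matrix or data.frame.
#' @param n_exposures number of exposures, default 3.
#' @param threshold variance fraction, default 0.95.
#' @param transform apply [transform_panel()] before the PCA (default `TRUE`).
#' @param use correlation handling of missing cells, see [effective_tests()].
#' @return list of class `"multiplicity_result"` with elements
#'   `n_components_95`, `n_exposures`, `n_tests`, `alpha`, `eigenvalues`.
#' @export
multiplicity_correction <- function(panel, n_exposures = 3, threshold = 0.95,
                                    transform = TRUE,
                                    use = c("complete", "pairwise")) {
  use <- match.arg(use)
  m <- if (transform) transform_panel(panel) else as.matrix(panel)
  n_eff <- effective_tests(m, threshold = threshold, use = use)
  res <- list(
    n_components_95 = as.integer(n_eff),
    n_exposures = as.integer(n_exposures),
    n_tests = as.integer(n_exposures) * as.integer(n_eff),
    alpha = bonferroni_threshold(n_exposures, n_eff),
    eigenvalues = attr(n_eff, "eigenvalues")
  )
  class(res) <- "multiplicity_result"
  res
}

#' @export
print.multiplicity_result <- function(x, ...) {
  cat(sprintf(
    "Effective tests: %d components x %d exposures = %d tests; alpha = %.3g\n",
    x$n_components_95, x$n_exposures, x$n_tests, x$alpha))
  invisible(x)
}
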