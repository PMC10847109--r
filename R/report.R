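# Triangulation: assemble per-pair estimates from the different arms,
# classify their consistency, and render forest-style tables.

#' Classify cross-method consistency for one exposure-metabolite pair
#'
#' Deterministic classification of a set of estimates (at least one
#' regression method and one MR method are expected, but any two or more
#' methods work):
#'
#' * `concordant` - all 95% CIs pairwise overlap and all signs agree;
#' * `mr-uninformative` - some MR CI is wider than
#'   `uninformative_ratio` times the narrowest regression CI (the
#'   weak-instrument pattern: parity MR at R^2 = 0.2%);
#' * `discordant` - some pair has conflicting signs with non-overlapping
#'   CIs;
#' * `partial` - anything else.
#'
#' Rules are applied in that order; since bias structures differ across
#' methods, consistency strengthens causal inference and the raw estimates
#' are always carried along so the classification is auditable.
#'
#' @param estimates named list of estimate rows ([effect_estimate()] or
#'   `"mr_estimate"`); names are the method labels. Methods whose label (or
#'   `method` field) contains `"ols"`, `"mv"` or `"model"` count as
#'   regression, the rest as MR.
#' @param alpha multiplicity-corrected significance threshold, default
#'   `0.05/54`.
#' @param exposure,metabolite labels carried into the record.
#' @param uninformative_ratio CI-width multiple above which MR is called
#'   uninformative, default 5.
#' @return list of class `"triangulation_record"`: labels, `estimates`,
#'   `passes_threshold` (named logical), `consistency`, `notes`.
#' @export
triangulate <- function(estimates, alpha = bonferroni_threshold(3, 18),
                        exposure = NA_character_,
                        metabolite = NA_character_,
                        uninformative_ratio = 5) {
  if (!length(estimates)) stop("empty estimate map")
  if (length(estimates) < 2L) stop("triangulation needs >= 2 methods")
  if (is.null(names(estimates)) || any(names(estimates) == ""))
    stop("`estimates` must be a named list")
  get1 <- function(e, f) e[[f]][1L]
  beta <- vapply(estimates, get1, numeric(1L), "beta")
  lo <- vapply(estimates, get1, numeric(1L), "ci_low")
  hi <- vapply(estimates, get1, numeric(1L), "ci_high")
  p <- vapply(estimates, get1, numeric(1L), "p")
  width <- hi - lo
  is_reg <- grepl("ols|mv|model", names(estimates), ignore.case = TRUE) |
    vapply(estimates, function(e)
      grepl("ols", get1(e, "method"), ignore.case = TRUE), logical(1L))

  pairs <- utils::combn(length(estimates), 2L)
  overlap <- apply(pairs, 2L, function(ij)
    lo[ij[1]] <= hi[ij[2]] && lo[ij[2]] <= hi[ij[1]])
  signs_agree <- apply(pairs, 2L, function(ij)
    sign(beta[ij[1]]) == sign(beta[ij[2]]))

  notes <- character(0)
  if (all(overlap) && all(signs_agree)) {
    consistency <- "concordant"
  } else if (any(is_reg) && any(!is_reg) &&
             any(width[!is_reg] > uninformative_ratio * min(width[is_reg]))) {
    consistency <- "mr-uninformative"
    notes <- c(notes, "MR confidence interval too wide to inform the comparison")
  } else if (any(!signs_agree & !overlap)) {
    consistency <- "discordant"
  } else {
    consistency <- "partial"
  }
  structure(list(
    exposure = exposure, metabolite = metabolite,
    estimates = estimates,
    passes_threshold = stats::setNames(p < alpha, names(estimates)),
    consistency = consistency, alpha = alpha, notes = notes
  ), class = "triangulation_record")
}

#' @export
print.triangulation_record <- function(x, ...) {
  cat(sprintf("%s ~ %s: %s (%s)\n", x$metabolite, x$exposure, x$consistency,
              paste(sprintf("%s %.3f%s", names(x$estimates),
                            vapply(x$estimates, function(e) e$beta[1L],
                                   numeric(1L)),
                            ifelse(x$passes_threshold, "*", "")),
                    collapse = "; ")))
  invisible(x)
}

#' Flatten triangulation records into a forest-style table
#'
#' One row per record-method combination with the point estimate, CI,
#' p-value and a filled/hollow significance marker at the multiplicity
#' threshold, ready for a forest plot or TSV export.
#'
#' @param records list of `"triangulation_record"` objects.
#' @param path optional TSV output path.
#' @return data.frame with columns `exposure`, `metabolite`, `method`,
#'   `beta`, `ci_low`, `ci_high`, `p`, `significant`, `marker`
#'   (`"filled"`/`"hollow"`), `consistency`.
#' @export
forest_table <- function(records, path = NULL) {
  if (!length(records)) stop("no records")
  if (inherits(records, "triangulation_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    do.call(rbind, lapply(names(r$estimates), function(m) {
      e <- r$estimates[[m]]
      sig <- unname(r$passes_threshold[[m]])
      data.frame(exposure = r$exposure, metabolite = r$metabolite,
                 method = m, beta = e$beta[1L], ci_low = e$ci_low[1L],
                 ci_high = e$ci_high[1L], p = e$p[1L],
                 significant = sig,
                 marker = if (sig) "filled" else "hollow",
                 consistency = r$consistency, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Forest plot of a triangulation table
#'
#' Per-metabolite point estimates and 95% CIs by method, filled points
#' marking associations passing the multiplicity threshold. Requires
#' `ggplot2`.
#'
#' @param table output of [forest_table()].
#' @return a ggplot object.
#' @export
forest_plot <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("forest_plot requires the ggplot2 package")
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$beta, y = .data$metabolite,
                               colour = .data$method,
                               shape = .data$marker)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2,
                            position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
    ggplot2::scale_shape_manual(values = c(filled = 16, hollow = 1)) +
    ggplot2::labs(x = "SD units per exposure unit", y = NULL) +
    ggplot2::theme_minimal()
}
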