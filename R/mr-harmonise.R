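# Harmonization of exposure and outcome GWAS summary statistics onto a
# common effect allele, the plumbing required before any two-sample MR.

.complement <- function(a) chartr("ACGT", "TGCA", toupper(a))

.is_palindromic <- function(ea, oa) .complement(ea) == oa

.check_sumstats <- function(x, what) {
  need <- c("SNP", "EA", "OA", "BETA", "SE")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, " summary statistics lack column(s): ",
         paste(miss, collapse = ", "))
  if (any(x$SE <= 0, na.rm = TRUE)) stop(what, " has non-positive SE")
  invisible(x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns per-SNP outcome associations to the exposure's effect allele.
#' Outcome betas are sign-flipped when the allele labels are swapped (directly
#' or after strand complementing). Palindromic SNPs (A/T or C/G) cannot be
#' resolved by allele labels alone: they are oriented by effect-allele
#' frequency concordance when both frequencies lie outside
#' `0.5 +/- palindrome_eaf_window`, and dropped otherwise. SNPs with
#' irreconcilable alleles are dropped. Every drop and flip is recorded in the
#' `log` attribute.
#'
#' @param exposure,outcome data.frames of summary statistics with columns
#'   `SNP`, `EA`, `OA`, `EAF`, `BETA`, `SE` (and optionally `P`, `N`), e.g.
#'   from [compute_summary_stats()] or [read_sumstats()].
#' @param palindrome_eaf_window half-width of the ambiguous EAF zone around
#'   0.5, default 0.08.
#' @return data.frame of class `"harmonized_set"` with one row per retained
#'   SNP: `snp`, `bx`, `bxse`, `by`, `byse`, `eaf`, `flipped`; attribute
#'   `log` is a data.frame recording actions and reasons per SNP.
#' @export
harmonise <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  .check_sumstats(exposure, "exposure")
  .check_sumstats(outcome, "outcome")
  common <- intersect(exposure$SNP, outcome$SNP)
  if (!length(common)) stop("no shared SNP identifiers between the two files")
  ex <- exposure[match(common, exposure$SNP), ]
  ou <- outcome[match(common, outcome$SNP), ]

  ea_e <- toupper(ex$EA); oa_e <- toupper(ex$OA)
  ea_o <- toupper(ou$EA); oa_o <- toupper(ou$OA)

  k <- length(common)
  keep <- rep(TRUE, k)
  flip <- rep(FALSE, k)
  action <- rep("aligned", k)
  reason <- rep(NA_character_, k)

  pal <- .is_palindromic(ea_e, oa_e)

  same <- ea_o == ea_e & oa_o == oa_e
  swap <- ea_o == oa_e & oa_o == ea_e
  # strand-complemented labels (only informative for non-palindromic SNPs)
  same_c <- .complement(ea_o) == ea_e & .complement(oa_o) == oa_e
  swap_c <- .complement(ea_o) == oa_e & .complement(oa_o) == ea_e

  for (i in seq_len(k)) {
    if (pal[i]) {
      if (!(same[i] || swap[i])) {
        keep[i] <- FALSE; action[i] <- "dropped"
        reason[i] <- "palindromic, allele labels do not match"
        next
      }
      eafs <- c(ex$EAF[i], ou$EAF[i])
      if (any(is.na(eafs)) ||
          any(abs(eafs - 0.5) <= palindrome_eaf_window)) {
        keep[i] <- FALSE; action[i] <- "dropped"
        reason[i] <- "palindromic, EAF too close to 0.5 to infer strand"
      } else if ((ex$EAF[i] - 0.5) * (ou$EAF[i] - 0.5) < 0) {
        flip[i] <- TRUE; action[i] <- "flipped"
        reason[i] <- "palindromic, orientation inferred from EAF"
      } else {
        reason[i] <- "palindromic, orientation inferred from EAF"
      }
    } else if (same[i] || same_c[i]) {
      # aligned as-is
    } else if (swap[i] || swap_c[i]) {
      flip[i] <- TRUE; action[i] <- "flipped"
      reason[i] <- "effect/other alleles swapped relative to exposure"
    } else {
      keep[i] <- FALSE; action[i] <- "dropped"
      reason[i] <- "irreconcilable alleles"
    }
  }

  by <- ifelse(flip, -ou$BETA, ou$BETA)
  set <- data.frame(
    snp = common, bx = ex$BETA, bxse = ex$SE, by = by, byse = ou$SE,
    eaf = if ("EAF" %in% names(ex)) ex$EAF else NA_real_,
    flipped = flip, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(set) <- NULL
  if (!nrow(set)) stop("harmonization dropped every SNP")
  attr(set, "log") <- data.frame(snp = common, action = action,
                                 reason = reason, stringsAsFactors = FALSE)
  class(set) <- c("harmonized_set", "data.frame")
  set
}

#' Harmonize two exposures and one outcome for multivariable MR
#'
#' Aligns both exposures' and the outcome's associations to the first
#' exposure's effect allele over the SNPs shared by all three files.
#'
#' @inheritParams harmonise
#' @param exposure2 summary statistics for the co-exposure (e.g. adult BMI).
#' @return a `"harmonized_set"` with additional columns `bx2`, `bx2se`.
#' @export
harmonise_mv <- function(exposure, exposure2, outcome,
                         palindrome_eaf_window = 0.08) {
  h1 <- harmonise(exposure, outcome, palindrome_eaf_window)
  h2 <- harmonise(exposure, exposure2, palindrome_eaf_window)
  common <- intersect(h1$snp, h2$snp)
  if (!length(common)) stop("no SNP retained across all three files")
  set <- h1[match(common, h1$snp), , drop = FALSE]
  i2 <- match(common, h2$snp)
  set$bx2 <- h2$by[i2]
  set$bx2se <- h2$byse[i2]
  rownames(set) <- NULL
  attr(set, "log") <- rbind(attr(h1, "log"), attr(h2, "log"))
  class(set) <- c("harmonized_set", "data.frame")
  set
}
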