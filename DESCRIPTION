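Package: reprotri
Title: Triangulating Effects of Female Reproductive Traits on Metabolic
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triangulating the effects of age at menarche, parity
    and age at natural menopause on panels of circulating metabolic measures.
    Implements the three analytical arms of the design side by side:
    multivariable linear regression with exposure categorisation,
    likelihood-ratio non-linearity tests and restricted cubic splines; a male
    negative-control comparison for parity; and Mendelian randomization, both
    two-sample (inverse-variance weighted, MR-Egger, weighted median,
    multivariable IVW, instrument-strength diagnostics, summary-statistic
    harmonization) and one-sample (weighted polygenic scores, two-stage least
    squares, polygenic-score Wald ratios, selected- versus full-sample
    contrasts). Includes rank-based inverse-normal transformation of
    metabolite panels, an effective-number-of-tests Bonferroni correction via
    principal component analysis, a cross-method triangulation classifier,
    and a synthetic cohort generator reproducing the causal and confounding
    structure the design assumes, so the full pipeline runs and is testable
    without access to individual-level biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
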