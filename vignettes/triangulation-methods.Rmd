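---
title: "Triangulating reproductive-trait effects on the metabolome: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating reproductive-trait effects on the metabolome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Age at menarche, parity and age at natural menopause mark key events of
female reproductive life, and each has been linked to later-life
cardiometabolic disease. Whether those links are causal is hard to settle
from any single observational design: multivariable regression is exposed to
residual confounding (socioeconomic position, childhood adiposity, adult
BMI); Mendelian randomization (MR) is exposed to horizontal pleiotropy,
weak instruments and sample-overlap bias; and, for menopause specifically,
complete-case regression silently restricts to women who have already
experienced a natural menopause — an age-linked selection. `reprotri`
implements the three designs side by side against a common metabolite panel
and classifies their agreement, on the principle that methods with
*different* bias structures lending the same answer strengthen causal
inference, while disagreement is itself diagnostic.

All outcome effects are expressed in SD units of the metabolite per unit of
the exposure (per year of menarche/menopause age, per additional child),
after rank-based inverse-normal transformation of each metabolite.

## The analytical arms

**Multivariable regression** (`fit_adjusted_model()`) fits OLS under three
covariate sets: model 1 unadjusted; model 2 adjusted for education, age at
baseline and recalled body size at age 10 (the primary causal model — these
are the confounders plausibly antecedent to the exposures); model 3
additionally adjusted for baseline BMI, smoking and alcohol. Model 3 is
deliberately ambiguous: if those baseline variables mediate the exposure
effect, adjusting for them removes signal rather than bias, which is why
attenuation from model 2 to model 3 is interpreted as evidence of
BMI-mediation rather than as the better estimate. Exposures are also
categorised (`categorize()`: menarche <13 / 13–14 / >14 years; menopause
<49 / 49–50 / 51–53 / >53 years; parity 0/1/2/3+) and non-linearity is
tested by a Gaussian likelihood-ratio test of category indicators against a
linear-in-scores term (`test_nonlinearity()`, df = k − 2). Scores are the
integer category indices 1..k; the choice is recorded in the output since
median-per-category scoring is an equally defensible convention. Where
non-linearity appears, restricted cubic splines with 3–5 knots at Harrell's
percentile positions are fitted (`fit_rcs()`); the truncated-power basis is
implemented from its closed form and constrained to be linear beyond the
boundary knots, and fits are compared to the linear model by AIC (BIC and
RMSE also reported).

**Male negative control** (`run_negative_control()`). Number of children in
men shares the socioeconomic and behavioural confounding of parity in women
but cannot carry the physiological effect of pregnancy. Estimates are fitted
per sex with identical covariate sets and classified: *causal-suggestive*
when the female association passes the multiplicity threshold while the male
one does not (or points the opposite way); *bias-suggestive* when the two
are directionally consistent with overlapping 95% CIs; *inconclusive*
otherwise. The causal check takes precedence: with a true female effect on
top of shared confounding, the female estimate is significant and both
descriptions can hold formally, and the male-null condition is the
discriminating observation. The significance threshold defaults to the
pipeline's Bonferroni alpha; a z-test of the female−male difference is
reported alongside so users can apply a different concordance rule. The
thresholds operationalise a criterion the source designs state only
qualitatively, so they are explicit parameters and the raw estimates are
always returned.

**Two-sample MR** (`harmonise()`, `mr_ivw()`, `mr_egger()`,
`mr_weighted_median()`, `mr_mvivw()`). Summary statistics are aligned to a
common effect allele; palindromic SNPs are oriented by allele-frequency
concordance only when both frequencies are outside 0.5 ± 0.08 and dropped
otherwise — dropping beats guessing at that boundary. IVW is weighted least
squares of outcome on exposure betas through the origin, with
multiplicative-random-effects SEs by default (`sqrt(max(1, Q/(k−1)))`
inflation; fixed-effect available by flag): the sources rarely state which
variant they used, and the multiplicative form is the defensive default in
the presence of heterogeneity. MR-Egger frees the intercept (average
directional pleiotropy under InSIDE) after orienting instruments to
positive exposure effects; its SEs use the unrestricted WLS residual
variance — flooring the variance at the fixed-effect value makes the Egger
interval visibly over-cover under homogeneity. The weighted median orders
per-SNP Wald ratios with first-order delta-method inverse-variance weights
and interpolates the weighted CDF at 0.5; its SE comes from a seeded
parametric bootstrap (1,000 draws by default) in which `bx` and `by` are
redrawn from their reported SEs. The bootstrap SD is mildly conservative
(about 10% in our calibration runs) — a known property of the recipe, kept
because it is the field standard. Multivariable IVW regresses outcome betas
on two exposure-beta columns without intercept, giving direct effects
conditional on the co-exposure (menarche accounting for adult BMI being the
canonical use). Instrument relevance is summarised by
`instrument_strength()`: per-SNP `r2 = 2 eaf (1−eaf) beta² / var(trait)`
and `F = r2 (n−2)/(1−r2)`. These formulas are our explicit convention — the
sources report R² and F without stating one — and the trait variance is a
required argument rather than an assumption. `negative_control_outcome_mr()`
applies IVW to outcomes that the exposures cannot affect (skin colour-like
variables) as a residual-stratification alarm.

**One-sample MR** (`build_pgs()`, `two_stage_least_squares()`,
`pgs_ratio()`). A weighted polygenic score instruments the exposure. 2SLS
reports the instrumental-variable SE (residuals from the observed, not
fitted, exposure; homoskedastic form, since the sources name only
"two-stage least squares"), plus the first-stage partial F with a warning
below 10. `pgs_ratio()` is the two-sample variant run on one cohort: the
PGS–outcome coefficient over the PGS–exposure coefficient with a
two-term delta-method SE, where the exposure association may be estimated
on a subsample. On identical samples and covariates it equals 2SLS
algebraically, which the tests verify numerically.
`selected_vs_full_contrast()` runs regression and one-sample MR on the
selected sample (women with an observed natural menopause age) and the
PGS ratio with the outcome association from all women — the comparison that
separates "regression vs MR" disagreement from "selected vs full sample"
disagreement.

**Multiplicity** (`effective_tests()`, `bonferroni_threshold()`). The
effective number of tests is the number of principal components of the
panel correlation matrix needed to reach 95% of total variance — 18 for the
default panel — so the threshold is 0.05/(3 × 18) = 0.05/54 ≈ 0.00093.
Correlation (not covariance) PCA on the rank-transformed panel, complete
rows by default; a pairwise-complete option exists but warns when the
resulting matrix has negative eigenvalues.

**Triangulation** (`triangulate()`): *concordant* when all CIs pairwise
overlap with agreeing signs; *mr-uninformative* when an MR interval is more
than 5× wider than the narrowest regression interval (the weak-instrument
pattern that parity MR shows at R² = 0.2%); *discordant* for conflicting
signs with disjoint intervals; *partial* otherwise. The 5× ratio and the
rule order are explicit configuration, and the estimates travel with the
verdict so any classification can be audited.

## What the synthetic generator emulates

`simulate_cohort()` produces the cohort the design assumes, so every stage
is testable without individual-level biobank access:

* **Latents.** Socioeconomic position and childhood adiposity drive
  education, recalled body size at age 10, adult BMI, all three exposures
  and (weakly) the metabolites — the confounding regression must block.
* **Genetics.** Independent HWE SNPs per exposure with half-normal effect
  sizes rescaled so the scores explain 7.4% (menarche), 0.2% (parity) and
  8.2% (menopause) of exposure variance. LD is deliberately absent: the
  emulated instrument lists are GWAS-pruned. A configurable share (default
  15%) of childhood-adiposity variance is driven by the menarche SNPs, so
  menarche instruments affect adult BMI both through menarche and through
  the shared adiposity path — the structure that makes multivariable MR
  informative and that matches the bidirectional menarche–BMI literature.
* **Bidirectional menarche–BMI.** Childhood adiposity lowers menarche age
  and raises adult BMI; menarche age has a residual path into adult BMI
  (−0.1 BMI SD per year). BMI in turn feeds several lipid measures, so
  menarche–lipid associations are BMI-mediated and attenuate under model 3
  or multivariable MR, by construction.
* **Metabolite panel.** 36 measures on 18 latent factors (two measures per
  factor, loading `sqrt(0.95)`), idiosyncratic noise 5%: within-pair
  correlation 0.95, so 17 components explain < 95% of variance and 18 reach
  it, reproducing an 18-effective-test panel. The factor calibration is our
  construction; the emulated platform states only the component count.
* **Menopause selection.** Latent menopause age exists for every woman;
  status is premenopausal for the 24.5% with the highest (menopause age −
  baseline age + noise) — hence younger women — surgical for 12.0% and
  "other" for 4.4% at random; observed menopause age is missing outside the
  natural stratum. With baseline age ~N(56.4, 8²) and menopause
  ~N(49.7, 5.1²), the age-ranked rule makes premenopausal women ~8 years
  younger on average, giving the old-skewed selected sample the contrast
  analyses need.
* **Age-modified menopause effect.** The menopause→LDL slope is
  −0.0068 SD/yr at the mean baseline age with +0.00102/yr of baseline age —
  solved from the emulated stratum estimates (−0.018 SD at ~45.5 years,
  +0.004 SD at ~67 years) — so stratum estimates flip sign across age and
  full-sample MR (which averages over younger women) is more negative than
  selected-sample regression.
* **Males** share every confounder and the children-count process but have
  no causal path to any metabolite and no reproductive columns: the
  negative-control ground truth.
* **Pleiotropy and stratification.** Invalid instruments get direct
  SNP→metabolite effects (balanced or directional); an optional scalar
  ancestry latent shifts allele frequencies and loads on negative-control
  outcome columns.

What the generator does **not** emulate: LD and imputation artefacts,
assay batch structure, non-Gaussian metabolite tails beyond what rank-INT
removes, couple/family structure, true longitudinal menopause transitions
(each woman has a single latent menopause age), and the exact marginal
distribution of parity (a rounded normal latent reproduces the mean,
spread and confounding of children counts, not the precise category
frequencies). Passing tests therefore show the estimators and the design
logic are correct under the assumed causal structure, not that real data
meet those assumptions.

## Numerical and design choices

* Rank-INT offset fixed at Blom's 3/8 (exposed as a parameter); ties take
  average ranks for determinism; the transform is computed on observed
  values only, and analyses are complete-case per
  exposure–outcome–model triple.
* CIs use the normal 1.96 multiplier throughout — intended sample sizes are
  in the tens of thousands.
* The LRT uses Gaussian likelihoods from the OLS fits; categories with
  fewer than 2 rows are dropped with a warning, and fewer than 3 occupied
  categories is an error rather than a silent df = 0.
* Spline knots default to Harrell's percentiles — (10, 50, 90),
  (5, 35, 65, 95), (5, 27.5, 50, 72.5, 95) — including for the 4-knot
  menopause spline, where only the knot count is specified by the emulated
  analysis.
* Harmonization drops rather than infers palindromic SNPs with EAF within
  0.08 of 0.5; every drop is logged with its reason.
* The weighted median sorts rows into a canonical order before the seeded
  bootstrap so results are invariant to input permutation.
* Monomorphic SNPs are flagged with `NA` estimates (their SE is undefined)
  rather than dropped silently.
* 2SLS covariates stand in for genotyping-array/ancestry-PC adjustments;
  the simulation has no batch structure, so they default to none but the
  interface accepts any covariate set.

## Calibration scenarios and problem sizes

The package's acceptance checks exercise each estimator in the regime its
assumptions describe: IVW with all instruments valid; MR-Egger under
directional pleiotropy with InSIDE satisfied; the weighted median with 30%
invalid instruments (under half the weight). Each uses 500 replicates of
the two-sample design with 100 SNPs and GWAS sizes of 50,000 per sample,
simulated at the summary-statistic level (sampling errors parameterised by
the sample sizes — the exact distribution the estimators see). The
robustness check uses 40% invalid instruments with directional effects
N(0.01, 0.005): large enough that the IVW interval sits above the truth
while the median stays within 3 SE of it. Design-signature runs use 100
seeds at 10,000 women (BMI attenuation), 100 seeds at 1,200 per sex
(negative control, with strong confounding ~0.12 SD/child on the
confounder-only metabolite and moderate ~0.03 on the causal one), and one
cohort of 208,062 women for the age-stratified and selected-vs-full
contrasts — the scale at which those analyses are designed to run, where
the selected sample comes out at ~123,000. These sizes are the package's
chosen study conditions and are stated here so results are reproducible.

## Known limitations

* Weighted-median bootstrap SEs are conservative (see above); coverage in
  the no-pleiotropy regime runs ≈97%.
* The trend-test scoring and the R²/F variance conventions are explicit
  choices among defensible alternatives; both are surfaced in outputs or
  arguments rather than hidden.
* With equal-strength shared confounding on all metabolites, the
  negative-control classifier cannot simultaneously achieve very high
  causal- and bias-detection rates at a Bonferroni threshold — the male
  estimate would need to be both clearly non-null (for sign concordance)
  and non-significant (for the causal call). The classifier is therefore
  best read per metabolite, with the reported z-difference as the
  continuous summary.
* Mixed-model GWAS, imputation QC, survey weights, robust/clustered SEs,
  MR-PRESSO-style outlier removal and non-linear MR are out of scope.
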