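make_stats <- function(snp, ea, oa, eaf, beta, se = 0.01) {
  data.frame(SNP = snp, EA = ea, OA = oa, EAF = eaf, BETA = beta, SE = se,
             P = 2 * pnorm(-abs(beta / se)), N = 10000,
             stringsAsFactors = FALSE)
}

test_that("harmonization aligns, flips and drops by the allele rules", {
  expo <- make_stats(c("s1", "s2", "s3", "s4"),
                     c("A", "G", "A", "C"), c("G", "C", "T", "A"),
                     c(0.3, 0.4, 0.50, 0.2), c(0.1, 0.2, 0.15, 0.1))
  outc <- make_stats(c("s1", "s2", "s3", "s4"),
                     c("G", "G", "A", "C"), c("A", "C", "T", "T"),
                     c(0.7, 0.4, 0.52, 0.2), c(0.2, 0.05, 0.1, 0.3))
  h <- harmonise(expo, outc)
  log <- attr(h, "log")
  # s1: swapped labels -> beta flipped
  expect_equal(h$by[h$snp == "s1"], -0.2)
  expect_true(h$flipped[h$snp == "s1"])
  # s2: aligned palindromic (G/C) with concordant EAFs away from 0.5 -> kept
  expect_true("s2" %in% h$snp)
  # s3: palindromic A/T with EAF ~ 0.5 -> dropped as unresolvable
  expect_false("s3" %in% h$snp)
  expect_match(log$reason[log$snp == "s3"], "EAF too close")
  # s4: C/A vs C/T irreconcilable -> dropped
  expect_false("s4" %in% h$snp)
  expect_match(log$reason[log$snp == "s4"], "irreconcilable")
  expect_error(harmonise(expo, make_stats("zz", "A", "G", 0.2, 0.1)),
               "no shared SNP")
})

test_that("strand-complemented outcome files harmonise to identical estimates", {
  set.seed(41)
  k <- 30
  bases <- c(A = "T", C = "G", G = "C", T = "A")
  ea <- sample(c("A", "C"), k, TRUE); oa <- ifelse(ea == "A", "G", "T")
  expo <- make_stats(sprintf("s%02d", 1:k), ea, oa,
                     runif(k, 0.15, 0.35), rnorm(k, 0.05, 0.02))
  outc <- make_stats(sprintf("s%02d", 1:k), ea, oa,
                     expo$EAF + rnorm(k, 0, 0.01), rnorm(k, 0.01, 0.02))
  # re-express a random half of the outcome file: swap alleles + negate beta,
  # and report another half on the opposite strand
  outc2 <- outc
  swap <- sample(k, 15)
  outc2$EA[swap] <- outc$OA[swap]; outc2$OA[swap] <- outc$EA[swap]
  outc2$BETA[swap] <- -outc$BETA[swap]
  outc2$EAF[swap] <- 1 - outc$EAF[swap]
  comp <- setdiff(seq_len(k), swap)
  outc2$EA[comp] <- bases[outc2$EA[comp]]; outc2$OA[comp] <- bases[outc2$OA[comp]]
  e1 <- mr_ivw(harmonise(expo, outc))
  e2 <- mr_ivw(harmonise(expo, outc2))
  expect_equal(e1$beta, e2$beta, tolerance = 1e-12)
  expect_equal(e1$se, e2$se, tolerance = 1e-12)
})

test_that("Wald ratio arithmetic and delta-method error", {
  w <- wald_ratio(bx = 0.5, bxse = 0.01, by = 0.05, byse = 0.02)
  expect_equal(w$beta, 0.1)
  expect_equal(w$se, 0.04)
  w0 <- wald_ratio(0.5, 0.01, 0, 0.02)
  expect_equal(w0$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "zero")
  # strong instrument: first-order SE within 10% of the two-term expansion
  se2 <- sqrt(0.02^2 / 0.5^2 + 0.05^2 * 0.01^2 / 0.5^4)
  expect_lt(abs(w$se - se2) / se2, 0.1)
})

test_that("IVW reduces correctly and reports heterogeneity", {
  set <- data.frame(bx = c(0.1, 0.2, 0.4), bxse = 0.01,
                    by = 0.3 * c(0.1, 0.2, 0.4), byse = c(0.01, 0.02, 0.015))
  e <- mr_ivw(set)
  expect_equal(e$beta, 0.3, tolerance = 1e-12)
  expect_lt(e$cochran_q, 1e-20)
  expect_identical(e$q_df, 2L)
  # with Q below its df, multiplicative random effects equals fixed
  expect_equal(e$se, mr_ivw(set, "fixed")$se)
  expect_error(mr_ivw(set[1, ]), "wald_ratio")
})

test_that("closed-form estimators match independent WLS oracles to 1e-10", {
  for (s in 1:25) {
    set <- random_set(40, seed = s)
    expect_equal(mr_ivw(set)$beta, oracle_ivw(set), tolerance = 1e-10)
    eg <- mr_egger(set)
    or <- oracle_egger(set)
    expect_equal(eg$slope$beta, or[["slope"]], tolerance = 1e-10)
    expect_equal(eg$intercept$beta, or[["intercept"]], tolerance = 1e-10)
    mv <- mr_mvivw(set)
    expect_equal(mv$beta, oracle_mvivw(set), tolerance = 1e-10)
  }
})

test_that("Egger fits an exact affine relation exactly", {
  bx <- c(0.05, 0.1, 0.2, 0.3)
  set <- data.frame(bx = bx, bxse = 0.01, by = 0.02 + 0.3 * bx,
                    byse = c(0.01, 0.03, 0.02, 0.01))
  eg <- mr_egger(set)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(eg$intercept$beta, 0.02, tolerance = 1e-12)
  expect_error(mr_egger(data.frame(bx = c(0.1, 0.1, 0.1), bxse = 0.01,
                                   by = 1:3 / 10, byse = 0.01)),
               "unidentified")
})

test_that("weighted median interpolates the weighted CDF and is robust", {
  # identical ratios: estimate equals them regardless of weights
  set <- data.frame(bx = c(1, 2, 4), bxse = 0.01,
                    by = 0.25 * c(1, 2, 4), byse = c(0.01, 0.05, 0.02))
  e <- mr_weighted_median(set, n_boot = 200, seed = 1)
  expect_equal(e$beta, 0.25, tolerance = 1e-12)

  # hand-evaluated interpolation: ratios (0.1, 0.2, 0.9), equal weights,
  # midpoints (1/6, 1/2, 5/6) -> CDF hits 0.5 exactly at the second ratio
  set2 <- data.frame(bx = c(1, 1, 1), bxse = 0.01,
                     by = c(0.1, 0.2, 0.9), byse = 1)
  e2 <- mr_weighted_median(set2, n_boot = 200, seed = 1)
  expect_equal(e2$beta, 0.2, tolerance = 1e-12)

  expect_warning(mr_weighted_median(set2, n_boot = 50, seed = 1), "unstable")
})

test_that("estimates are permutation-invariant and scale-equivariant", {
  set <- random_set(30, seed = 7)
  perm <- sample(30)
  a <- mr_weighted_median(set, n_boot = 300, seed = 11)
  b <- mr_weighted_median(set[perm, ], n_boot = 300, seed = 11)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  expect_identical(mr_ivw(set)$beta, mr_ivw(set[perm, ])$beta)

  # rescaling outcome betas and SEs by c rescales estimates by c
  cc <- 3.7
  sc <- set; sc$by <- cc * sc$by; sc$byse <- cc * sc$byse
  expect_equal(mr_ivw(sc)$beta, cc * mr_ivw(set)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(sc)$se, cc * mr_ivw(set)$se, tolerance = 1e-12)
  expect_equal(mr_egger(sc)$slope$beta, cc * mr_egger(set)$slope$beta,
               tolerance = 1e-12)
  am <- mr_weighted_median(sc, n_boot = 300, seed = 11)
  expect_equal(am$beta, cc * a$beta, tolerance = 1e-12)
  expect_equal(am$se, cc * a$se, tolerance = 1e-10)
})

test_that("multivariable IVW nests the univariable estimator", {
  set <- random_set(40, seed = 13)
  # co-exposure identically zero: dropped, estimate equals univariable IVW
  set0 <- set; set0$bx2 <- 0
  mv <- suppressMessages(mr_mvivw(set0))
  expect_equal(nrow(mv), 1L)
  expect_equal(mv$beta, mr_ivw(set)$beta, tolerance = 1e-12)
  expect_error(mr_mvivw(data.frame(bx = c(1, 2), bxse = 1,
                                   by = c(1, 2), byse = 1, bx2 = c(2, 4))),
               ">= 3")
})

test_that("conditioning on the mediator removes a fully mediated effect", {
  # exposure 1 affects the outcome only through exposure 2 (BMI-like):
  # univariable effect is the product path, direct effect is null
  set.seed(17)
  k <- 100
  bx <- abs(rnorm(k, 0.05, 0.03))
  gamma <- rnorm(k, 0, 0.02)          # direct SNP effects on exposure 2
  bx2 <- -0.4 * bx + gamma            # exposure 2 = mediator
  byse <- rep(0.004, k)
  by <- 0.25 * bx2 + rnorm(k, 0, byse)   # outcome via exposure 2 only
  set <- data.frame(bx = bx, bxse = 0.005, by = by, byse = byse, bx2 = bx2)
  uni <- mr_ivw(set)
  mv <- mr_mvivw(set)
  direct <- mv[mv$method == "mvmr_ivw:bx", ]
  expect_lt(abs(uni$beta - (-0.1)), 3 * uni$se)   # total = 0.25 * -0.4
  expect_lt(abs(direct$beta), 3 * direct$se)      # direct ~ 0
  expect_gt(abs(uni$beta), 3 * uni$se)
})

test_that("instrument strength follows the plug-in formulas", {
  rec <- data.frame(EAF = 0.5, BETA = 0.1, N = 1002)
  st <- instrument_strength(rec, trait_variance = 1)
  expect_equal(st$r2_total, 0.005)
  expect_equal(st$mean_f, 0.005 * 1000 / 0.995)
  st0 <- instrument_strength(data.frame(EAF = 0.3, BETA = 0, N = 100), 1)
  expect_equal(st0$r2_total, 0)
  expect_equal(st0$mean_f, 0)
  expect_error(instrument_strength(rec, 0), "positive")
})

test_that("negative-control outcome MR flags only real stratification", {
  # null outcome: flag rate near alpha
  set.seed(19)
  flags <- vapply(1:300, function(i) {
    s <- simulate_summary_mr(n_snps = 30, beta = 0, r2 = 0.05)
    negative_control_outcome_mr(s)$stratification_flag
  }, logical(1))
  expect_lte(mean(flags), 0.05 * 1.5 + 3 * sqrt(0.05 * 0.95 / 300))

  # ancestry-structured generator: exposure score and the negative-control
  # outcome share the ancestry latent, IVW flags it
  cfg <- sim_config(n_females = 8000, n_males = 0, n_snps_per_exposure = 60,
                    stratification = list(effect = 0.4, outcome_loading = 1),
                    seed = 5)
  sim <- simulate_cohort(cfg)
  fem <- sim$cohort[sim$cohort$sex == "female", ]
  ssx <- compute_summary_stats(sim$genotypes$menopause, fem$menopause_latent)
  ssy <- compute_summary_stats(sim$genotypes$menopause, fem$skin_tone)
  set <- data.frame(bx = ssx$BETA, bxse = ssx$SE, by = ssy$BETA,
                    byse = ssy$SE)
  expect_true(negative_control_outcome_mr(set)$stratification_flag)
  expect_error(mr_ivw(set[0, ]), "2 SNPs")
})
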