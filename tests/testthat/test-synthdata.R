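test_that("genotypes are drawn under Hardy-Weinberg equilibrium", {
  cfg <- sim_config(n_females = 50000, n_snps_per_exposure = 5,
                    maf_range = c(0.3, 0.3), seed = 2)
  g <- simulate_genotypes(cfg)
  # chi-square against exact HWE class expectations (0.49, 0.42, 0.09) * n
  expected <- c(0.49, 0.42, 0.09) * nrow(g)
  for (j in seq_len(ncol(g))) {
    obs <- tabulate(g[, j] + 1L, nbins = 3L)
    chi <- sum((obs - expected)^2 / expected)
    expect_lt(chi, qchisq(0.999, df = 2))
  }
})

test_that("allele-frequency symmetry and degenerate MAF behave", {
  cfg <- sim_config(n_females = 100000, n_snps_per_exposure = 3,
                    maf_range = c(0.5, 0.5), seed = 6)
  g <- simulate_genotypes(cfg)
  expect_true(all(abs(colMeans(g) - 1) < 3 * sqrt(0.5 / 100000)))
  expect_true(all(g %in% 0:2))
  # maf = 0 degenerate draw (test-only path): all-zero column
  g0 <- reprotri:::.draw_genotypes(200, c(0, 0.2))
  expect_true(all(g0[, 1] == 0))
  expect_error(simulate_genotypes(cfg, n = 0), "positive")
})

test_that("identical seeds give bit-identical cohorts; different seeds differ", {
  a <- simulate_cohort(small_config(seed = 9))
  b <- simulate_cohort(small_config(seed = 9))
  d <- simulate_cohort(small_config(seed = 10))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$genotypes, b$genotypes)
  expect_false(identical(a$cohort$menarche_age, d$cohort$menarche_age))
})

test_that("cohort structure matches the design: missingness, sexes, validity", {
  sim <- simulate_cohort(sim_config(n_females = 20000, n_males = 500,
                                    n_snps_per_exposure = 5, seed = 4))
  fem <- sim$cohort[sim$cohort$sex == "female", ]
  mal <- sim$cohort[sim$cohort$sex == "male", ]

  # premenopausal + surgical + other fractions reproduce the design margins
  frac_missing <- mean(is.na(fem$menopause_age))
  expect_lt(abs(frac_missing - 0.409), 3 * sqrt(0.409 * 0.591 / 20000) + 0.01)
  expect_true(all(is.na(fem$menopause_age[fem$menopause_status != "natural"])))

  # premenopausal women are younger (age-linked selection)
  expect_lt(mean(fem$age_baseline[fem$menopause_status == "pre"]),
            mean(fem$age_baseline[fem$menopause_status == "natural"]) - 3)

  # males carry no reproductive columns but share children counts
  expect_true(all(is.na(mal$menarche_age)))
  expect_true(all(is.na(mal$menopause_age)))
  expect_true(all(mal$n_children >= 0))

  # metabolites finite after transformation
  expect_true(all(is.finite(transform_panel(fem[, sim$metabolites]))))

  # statin prevalence near the emulated 11.3%
  expect_lt(abs(mean(sim$cohort$statin_flag) - 0.113), 0.02)
})

test_that("unknown metabolite names in causal effects are rejected", {
  expect_error(
    sim_config(causal_effects = list(menarche = c(nope = 0.1),
                                     parity = c(), menopause = c())),
    "unknown metabolite")
  expect_error(sim_config(menopause_missing = list(premenopausal_frac = 0.6,
                                                   surgical_frac = 0.5,
                                                   other_frac = 0)),
               "must be < 1")
})

test_that("null configuration severs exposure-metabolite associations", {
  # with all causal and confounder paths zeroed, per-metabolite slopes on
  # the exposure are null for at least 95% of metabolite-seed pairs
  hits <- 0L; total <- 0L
  for (s in 1:25) {
    sim <- simulate_cohort(sim_config(n_females = 500, n_males = 0,
                                      n_snps_per_exposure = 5, seed = s) |>
                             null_config())
    fem <- sim$cohort[sim$cohort$sex == "female", ]
    x <- fem$menarche_age
    for (m in sim$metabolites) {
      f <- summary(lm(fem[[m]] ~ x))$coefficients
      total <- total + 1L
      if (abs(f[2, 1]) < 3 * f[2, 2]) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("summary statistics recover generative slopes and null uniformity", {
  set.seed(8)
  n <- 20000
  g <- reprotri:::.draw_genotypes(n, rep(0.3, 3))
  colnames(g) <- c("a", "b", "c")
  y <- 0.2 * g[, 1] + rnorm(n)
  ss <- compute_summary_stats(g, y)
  expect_lt(abs(ss$BETA[1] - 0.2), 3 * ss$SE[1])
  expect_equal(ss$N[1], n)

  # phenotype independent of genotypes: p-values uniform (KS at 0.001)
  set.seed(9)
  g2 <- reprotri:::.draw_genotypes(2000, runif(500, 0.1, 0.5))
  y2 <- rnorm(2000)
  ss2 <- compute_summary_stats(g2, y2)
  expect_gt(suppressWarnings(ks.test(ss2$P, "punif")$p.value), 0.001)
})

test_that("summary statistics are invariant to joint row permutation and flag monomorphs", {
  set.seed(10)
  g <- reprotri:::.draw_genotypes(500, c(0.2, 0.4))
  g <- cbind(g, 0L)  # monomorphic column
  y <- rnorm(500) + 0.1 * g[, 1]
  cov <- data.frame(c1 = rnorm(500))
  perm <- sample(500)
  a <- compute_summary_stats(g, y, cov)
  b <- compute_summary_stats(g[perm, ], y[perm], cov[perm, , drop = FALSE])
  expect_equal(a$BETA, b$BETA)
  expect_equal(a$SE, b$SE)
  expect_true(a$monomorphic[3])
  expect_true(is.na(a$SE[3]))
})

test_that("simulated instrument tables carry the configured variance explained", {
  ss <- simulate_instrument_stats(n_snps = 200, r2 = 0.074, n = 300000,
                                  trait_variance = 2.56, seed = 42)
  st <- instrument_strength(ss, trait_variance = 2.56)
  expect_lt(abs(st$r2_total - 0.074) / 0.074, 0.1)
  expect_lt(abs(st$mean_f - 300000 * 0.074 / 200) / (300000 * 0.074 / 200),
            0.15)
})
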