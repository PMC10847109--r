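test_that("exposure categorisation uses the published cut-points", {
  m <- categorize("menarche", c(12.9, 13.0, 14.9, 15.0))
  expect_equal(as.character(m), c("<13", "13-14", "13-14", ">14"))
  p <- categorize("parity", c(0, 1, 2, 3, 7))
  expect_equal(as.character(p), c("0", "1", "2", "3+", "3+"))
  q <- categorize("menopause", c(48.9, 49, 50.9, 51, 53.9, 54))
  expect_equal(as.character(q),
               c("<49", "49-50", "49-50", "51-53", "51-53", ">53"))
  expect_error(categorize("parity", c(-1, 2)), "negative parity")
  expect_true(is.na(categorize("menarche", NA_real_)))
})

test_that("adjusted models recover generative slopes when covariates match confounders", {
  set.seed(21)
  n <- 6000
  conf <- rnorm(n)
  d <- data.frame(
    education = factor(sample(c("low", "high"), n, TRUE, prob = c(0.5, 0.5))),
    age_baseline = rnorm(n, 56, 8),
    body_size_age10 = cut(conf, c(-Inf, -0.5, 0.5, Inf),
                          labels = c("thinner", "average", "plumper"))
  )
  d$menarche_age <- 13 - 0.5 * conf + rnorm(n, 0, 1.5)
  d$y <- 0.05 * d$menarche_age + 0.3 * conf +
    0.1 * (d$education == "high") + rnorm(n)
  e1 <- fit_adjusted_model(d, "menarche", "y", "model1")
  e2 <- fit_adjusted_model(d, "menarche", "y", "model2")
  # model2 blocks the (coarsened) confounder path much better than model1
  expect_lt(abs(e2$beta - 0.05), 3 * e2$se)
  expect_gt(abs(e1$beta - 0.05), abs(e2$beta - 0.05))
  expect_equal(e2$ci_high - e2$beta, 1.96 * e2$se)

  # permuted exposure is null
  d$menarche_perm <- sample(d$menarche_age)
  e0 <- fit_adjusted_model(d, "menarche_perm", "y", "model1")
  expect_lt(abs(e0$beta), 3 * e0$se)
})

test_that("model estimates coincide when covariates are independent noise", {
  set.seed(22)
  n <- 4000
  d <- data.frame(
    education = factor(sample(letters[1:3], n, TRUE)),
    age_baseline = rnorm(n, 56, 8),
    body_size_age10 = factor(sample(c("thinner", "average", "plumper"), n, TRUE)),
    bmi = rnorm(n, 27, 5),
    smoking = factor(sample(c("never", "prev", "cur"), n, TRUE)),
    alcohol = factor(sample(c("lo", "hi"), n, TRUE)),
    menarche_age = rnorm(n, 13, 1.6)
  )
  d$y <- 0.04 * d$menarche_age + rnorm(n)
  b <- vapply(c("model1", "model2", "model3"), function(m)
    fit_adjusted_model(d, "menarche", "y", m)$beta, numeric(1))
  expect_lt(max(b) - min(b), 0.01)
})

test_that("collinear covariates are reported by name", {
  set.seed(23)
  d <- data.frame(
    education = factor(sample(letters[1:2], 200, TRUE)),
    age_baseline = rnorm(200), menarche_age = rnorm(200), y = rnorm(200)
  )
  d$body_size_age10 <- d$age_baseline  # exact copy
  expect_error(fit_adjusted_model(d, "menarche", "y", "model2"),
               "collinear", ignore.case = TRUE)
})

test_that("non-linearity LRT detects curvature and flags degenerate categories", {
  set.seed(24)
  n <- 50000
  d <- data.frame(menarche_age = runif(n, 10, 17))
  sc <- as.integer(categorize("menarche", d$menarche_age))
  d$y <- 0.05 * (sc - 2)^2 + rnorm(n)   # pure quadratic in category scores
  r <- test_nonlinearity(d, "menarche", "y", "model1")
  expect_lt(r$p_nonlinear, 0.001)
  expect_identical(r$df, 1L)

  # only two occupied categories: degenerate
  d2 <- data.frame(menarche_age = c(rep(12, 50), rep(13.5, 50)),
                   y = rnorm(100))
  expect_error(test_nonlinearity(d2, "menarche", "y", "model1"),
               ">= 3 occupied")

  # a nearly-empty category is dropped with a warning
  d3 <- data.frame(menopause_age = c(rep(45, 300), rep(49.5, 300),
                                     rep(52, 300), 60),
                   y = rnorm(901))
  expect_warning(r3 <- test_nonlinearity(d3, "menopause", "y", "model1"),
                 "dropping category")
  expect_equal(length(r3$categories), 3L)
})

test_that("trend p-value is well calibrated under a linear truth", {
  set.seed(25)
  n <- 3000
  d <- data.frame(n_children = sample(0:5, n, TRUE))
  sc <- as.integer(categorize("parity", d$n_children))
  d$y <- 0.1 * sc + rnorm(n)
  r <- test_nonlinearity(d, "parity", "y", "model1")
  expect_lt(r$p_trend, 1e-6)       # trend present
  expect_gt(r$p_nonlinear, 0.001)  # no curvature beyond trend
})

test_that("medication exclusion filters the flagged rows only", {
  d <- data.frame(statin_flag = c(TRUE, FALSE, FALSE, TRUE),
                  hrt_flag = c(FALSE, TRUE, FALSE, FALSE), x = 1:4)
  expect_message(out <- exclude_medication(d, "statin"), "excluding 2")
  expect_equal(out$x, c(2, 3))
  both <- suppressMessages(exclude_medication(d, "both"))
  expect_lte(nrow(both), nrow(out))
  none <- data.frame(statin_flag = rep(FALSE, 3), hrt_flag = rep(FALSE, 3))
  expect_equal(nrow(suppressMessages(exclude_medication(none, "both"))), 3)
})

test_that("age stratification partitions on the stated boundaries", {
  d <- data.frame(age_baseline = c(40, 50.0, 50.1, 58, 58.1, 63, 63.1, 70))
  s <- age_stratify(d)
  expect_equal(s$age_le50$age_baseline, c(40, 50.0))
  expect_equal(s$age_50_58$age_baseline, c(50.1, 58))
  expect_equal(s$age_58_63$age_baseline, c(58.1, 63))
  expect_equal(s$age_gt63$age_baseline, c(63.1, 70))
  expect_equal(sum(vapply(s, nrow, integer(1))), nrow(d))

  empty <- age_stratify(data.frame(age_baseline = numeric(0)))
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
  expect_warning(age_stratify(data.frame(age_baseline = c(45, NA))),
                 "missing age")
})
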