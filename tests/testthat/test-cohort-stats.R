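test_that("one-way ANOVA matches the hand decomposition", {
  # groups {0,2} and {2,4}: SSb = 4, SSw = 4, F = (4/1)/(4/2) = 2
  res <- anova_oneway(c(0, 2, 2, 4), c("a", "a", "b", "b"))
  expect_equal(res$statistic, 2)
  expect_equal(res$df, c(1, 2))
  # identical group means
  expect_equal(anova_oneway(c(1, 3, 1, 3), c("a", "a", "b", "b"))$statistic,
               0)
  # four groups of the cohort's sizes give denominator df 188
  set.seed(5)
  g <- rep(c("CN", "EMCI", "LMCI", "AD"), c(69, 52, 41, 30))
  expect_equal(anova_oneway(rnorm(192), g)$df, c(3, 188))
  expect_error(anova_oneway(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "variance")
})

test_that("summary-statistics ANOVA is exactly equivalent to raw ANOVA", {
  expect_equal(anova_from_summary(c(2, 2), c(1, 3), c(sqrt(2), sqrt(2)))$
                 statistic, 2)
  expect_equal(anova_from_summary(c(5, 8), c(2, 2), c(1, 3))$statistic, 0)
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(2:5, 1)
    g <- factor(rep(seq_len(k), times = sample(3:12, k, replace = TRUE)))
    x <- rnorm(length(g), mean = as.integer(g))
    raw <- anova_oneway(x, g)
    smry <- anova_from_summary(tabulate(g), tapply(x, g, mean),
                               tapply(x, g, sd))
    expect_equal(smry$statistic, raw$statistic, tolerance = 1e-10)
    expect_identical(smry$df, raw$df)
  }
  expect_error(anova_from_summary(c(1, 5), c(0, 1), c(1, 1)), "n >= 2")
})

test_that("Pearson chi-square matches the expected-count oracle", {
  res0 <- chi_square_counts(matrix(10, 2, 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$df, 1L)

  obs <- matrix(c(20, 10, 10, 20), 2, 2)
  # brute-force oracle
  E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  x2_oracle <- sum((obs - E)^2 / E)
  res <- chi_square_counts(obs)
  expect_equal(res$statistic, x2_oracle)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)   # 6.667

  expect_equal(chi_square_counts(matrix(1:8, 4, 2))$df, 3L)
  expect_error(chi_square_counts(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("post-hoc pairs use the Bonferroni-corrected threshold", {
  set.seed(9)
  g <- rep(c("CN", "EMCI", "LMCI", "AD"), each = 20)
  x <- rnorm(80)
  res <- posthoc_pairwise(x, g, reference = "AD", alpha_family = 0.05)
  expect_equal(nrow(res), 3L)
  expect_equal(unique(res$threshold), 0.05 / 3, tolerance = 1e-12)
  expect_false(any(res$significant))      # identical groups

  x[g == "AD"] <- x[g == "AD"] + 10      # 10-SD shift
  res2 <- posthoc_pairwise(x, g, reference = "AD")
  expect_true(all(res2$significant))
  res_all <- posthoc_pairwise(x, g)
  expect_equal(nrow(res_all), 6L)
  expect_equal(unique(res_all$threshold), 0.05 / 6)
})

test_that("partial correlation equals the residualization oracle", {
  set.seed(11)
  n <- 60
  C <- data.frame(age = rnorm(n, 70, 7), gender = rbinom(n, 1, 0.5))
  x <- rnorm(n) + 0.1 * C$age
  expect_equal(partial_correlation(x, x + 0 * C$age, C)$statistic, 1)

  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    res <- partial_correlation(x, y, C)
    X <- cbind(1, as.matrix(C))
    r_oracle <- cor(lm.fit(X, x)$residuals, lm.fit(X, y)$residuals)
    expect_equal(res$statistic, r_oracle, tolerance = 1e-12)
    expect_equal(res$df, n - 2 - 2)
    # invariance under affine rescaling of covariates
    C2 <- data.frame(age = 3 * C$age - 100, gender = 5 * C$gender + 1)
    expect_equal(partial_correlation(x, y, C2)$statistic, res$statistic,
                 tolerance = 1e-10)
  }

  # constructed orthogonality: y orthogonal to x and covariates
  x0 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  y0 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  expect_equal(partial_correlation(x0, y0, NULL)$statistic, 0,
               tolerance = 1e-14)
  expect_error(partial_correlation(x0, rep(1, 8), NULL), "constant")
})

test_that("ANOVA and partial correlation hold their nominal size", {
  set.seed(2026)
  n_rep <- 1000
  g <- rep(1:4, each = 10)
  C <- matrix(rnorm(30 * 2), 30, 2)
  p_anova <- p_pc <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    p_anova[i] <- anova_oneway(rnorm(40), g)$p
    p_pc[i] <- partial_correlation(rnorm(30), rnorm(30), C)$p
  }
  expect_gte(mean(p_anova < 0.05), 0.03)
  expect_lte(mean(p_anova < 0.05), 0.07)
  expect_gte(mean(p_pc < 0.05), 0.03)
  expect_lte(mean(p_pc < 0.05), 0.07)
})

test_that("cohort_table1 produces one row and one test per variable", {
  cohort <- score_cohort(generate_cohort(small_truth()))
  t1 <- cohort_table1(cohort)
  expect_setequal(t1$summary$variable,
                  c("age", "mmse", "adas_cog", "vrf_score", "gender",
                    "apoe4"))
  expect_true(all(vapply(t1$tests, function(x) x$p, 1) >= 0))
  expect_named(t1$summary, c("variable", "CN", "EMCI", "LMCI", "AD", "p"))
})
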