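make_images <- function(mat, dims) {
  # one tiny volume per row of mat (V = prod(dims) columns)
  lapply(seq_len(nrow(mat)), function(i) array(mat[i, ], dim = dims))
}

test_that("design matrix layout, coding and rank checks", {
  cohort <- score_cohort(generate_cohort(small_truth()))
  X <- build_design(cohort, "vrf_score")
  expect_equal(ncol(X), 6L)           # intercept + predictor + 4 covariates
  expect_identical(colnames(X)[1:2], c("(Intercept)", "vrf_score"))
  expect_equal(attr(X, "predictor_index"), 2L)

  Xg <- build_design(cohort, "vrf_score", include_group = TRUE)
  expect_equal(ncol(Xg), 9L)          # + 3 group dummies
  # swapping in a cognitive predictor gives the same shape
  expect_equal(dim(build_design(cohort, "mmse")), dim(X))

  cohort$const <- 1
  expect_error(build_design(cohort, "const"), "rank deficient.*const")
  expect_error(build_design(cohort, "nope"), "missing")
})

test_that("exact linear construction is recovered voxel-wise", {
  set.seed(21)
  n <- 24; dims <- c(4, 4, 2)
  cohort <- data.frame(vrf_score = sample(0:4, n, TRUE),
                       age = rnorm(n, 72, 6), gender = rbinom(n, 1, 0.5),
                       education = sample(12:20, n, TRUE),
                       apoe4 = rbinom(n, 1, 0.4))
  Y <- matrix(3, n, prod(dims)) + 2 * cohort$vrf_score
  fit <- fit_glm(make_images(Y, dims), array(TRUE, dims),
                 build_design(cohort, "vrf_score"))
  expect_equal(unname(fit$beta$data[fit$beta$mask]),
               rep(2, prod(dims)), tolerance = 1e-10)
  expect_equal(fit$df, n - 6)
})

test_that("voxel-wise fit equals the normal-equations oracle", {
  set.seed(22)
  n <- 30; V <- 50; dims <- c(5, 5, 2)
  cohort <- data.frame(vrf_score = rnorm(n), age = rnorm(n, 70, 5),
                       gender = rbinom(n, 1, 0.5),
                       education = rnorm(n, 16, 2),
                       apoe4 = rbinom(n, 1, 0.3))
  X <- build_design(cohort, "vrf_score")
  Y <- matrix(rnorm(n * V), n, V)
  fit <- fit_glm(make_images(Y, dims), array(TRUE, dims), X)
  for (v in sample(V, 10)) {
    orc <- ols_oracle(X, Y[, v])
    expect_equal(fit$beta$data[v], orc$beta[2], tolerance = 1e-10)
    expect_equal(fit$t$data[v], orc$t[2], tolerance = 1e-10)
  }
})

test_that("permutation null keeps the voxel-wise false-positive rate", {
  set.seed(23)
  n <- 40; V <- 1000
  x <- rnorm(n)
  Y <- matrix(rnorm(n * V), n, V)
  cohort <- data.frame(x = sample(x))     # permuted predictor
  X <- cbind(1, cohort$x); colnames(X) <- c("(Intercept)", "x")
  attr(X, "predictor_index") <- 2L
  fit <- fit_glm(make_images(Y, c(10, 10, 10)), array(TRUE, c(10, 10, 10)),
                 X)
  p <- 2 * pt(-abs(fit$t$data), fit$df)
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("t maps are invariant to intensity scaling; betas scale", {
  set.seed(24)
  n <- 20; dims <- c(3, 3, 2)
  x <- rnorm(n)
  Y <- matrix(rnorm(n * prod(dims)), n) + x
  X <- cbind(`(Intercept)` = 1, x = x)
  f1 <- fit_glm(make_images(Y, dims), array(TRUE, dims), X)
  f2 <- fit_glm(make_images(10 * Y, dims), array(TRUE, dims), X)
  expect_equal(f2$t$data, f1$t$data, tolerance = 1e-10)
  expect_equal(f2$beta$data, 10 * f1$beta$data, tolerance = 1e-10)
  # centering covariates leaves the predictor's beta unchanged
  C <- rnorm(n)
  Xc1 <- cbind(X, C = C); Xc2 <- cbind(X, C = C - mean(C))
  attr(Xc1, "predictor_index") <- attr(Xc2, "predictor_index") <- 2L
  g1 <- fit_glm(make_images(Y, dims), array(TRUE, dims), Xc1)
  g2 <- fit_glm(make_images(Y, dims), array(TRUE, dims), Xc2)
  expect_equal(g1$beta$data, g2$beta$data, tolerance = 1e-10)
})

test_that("single-predictor GLM reproduces the Pearson-correlation t", {
  set.seed(25)
  n <- 35
  x <- rnorm(n); y <- rnorm(n) + 0.4 * x
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_glm(make_images(matrix(y, n, 1), c(1, 1, 1)),
                 array(TRUE, c(1, 1, 1)), X)
  r <- cor(x, y)
  t_r <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(fit$t$data[1], t_r, tolerance = 1e-10)
})

test_that("t-to-z is probability-preserving and near-identity at high df", {
  t <- seq(-4, 4, by = 0.5)
  z <- t_to_z(t, 400)
  expect_equal(pnorm(-abs(z)), pt(-abs(t), 400), tolerance = 1e-12)
  expect_true(all(abs(z - t)[t != 0] / abs(t)[t != 0] < 0.02))
  expect_equal(sign(z), sign(t))
  # no underflow for extreme statistics
  expect_true(is.finite(t_to_z(40, 100)) && t_to_z(40, 100) > 10)
})

test_that("zero-residual voxels are flagged, not dropped", {
  n <- 12; dims <- c(2, 2, 1)
  x <- rnorm(n)
  Y <- cbind(2 * x, matrix(rnorm(3 * n), n))   # voxel 1 is noiseless
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_glm(make_images(Y, dims), array(TRUE, dims), X)
  expect_equal(fit$degenerate_voxels, 1L)
  expect_true(is.infinite(fit$t$data[1]))
})

test_that("ANCOVA F-map equals the nested sums-of-squares oracle", {
  set.seed(26)
  n <- 40; dims <- c(4, 4, 2); V <- prod(dims)
  g <- factor(rep(1:4, each = 10))
  C <- data.frame(age = rnorm(n), apoe = rbinom(n, 1, 0.3))
  Y <- matrix(rnorm(n * V), n)
  fit <- fit_ancova(make_images(Y, dims), array(TRUE, dims), g, C)
  expect_equal(fit$df, c(3, n - 6))
  Xr <- cbind(1, as.matrix(C))
  Xf <- cbind(Xr, sapply(levels(g)[-1], function(l) as.numeric(g == l)))
  for (v in sample(V, 10)) {
    rss_r <- sum(lm.fit(Xr, Y[, v])$residuals^2)
    rss_f <- sum(lm.fit(Xf, Y[, v])$residuals^2)
    f_orc <- ((rss_r - rss_f) / 3) / (rss_f / (n - 6))
    expect_equal(fit$F$data[v], f_orc, tolerance = 1e-10)
  }
})

test_that("ANCOVA detects a constructed group deficit and not a null", {
  set.seed(27)
  n <- 40; dims <- c(6, 6, 4); V <- prod(dims)
  g <- factor(rep(1:4, each = 10))
  Y <- matrix(rnorm(n * V, sd = 1), n)
  roi <- 1:20
  Y[g == "4", roi] <- Y[g == "4", roi] - 5      # 5 x noise SD deficit
  fit <- fit_ancova(make_images(Y, dims), array(TRUE, dims), g)
  fcrit <- qf(0.999, fit$df[1], fit$df[2])
  expect_true(all(fit$F$data[roi] > fcrit))
  expect_lt(mean(fit$F$data[-roi] > fcrit), 0.05)
  expect_error(fit_ancova(make_images(Y, dims), array(TRUE, dims),
                          factor(c(1, rep(2:4, 13)))), "n >= 2")
})
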