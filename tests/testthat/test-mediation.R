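test_that("hand-computed OLS paths on the worked four-point example", {
  # X = 0..3, M = (1,0,3,2), Y = M: a = cov/var = 3/5 = 0.6, b = 1, c' = 0
  fit <- fit_mediation(x = c(0, 1, 2, 3), m = c(1, 0, 3, 2),
                       y = c(1, 0, 3, 2))
  expect_equal(fit$a, 0.6, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$c_prime, 0, tolerance = 1e-12)
  expect_equal(fit$c, 0.6, tolerance = 1e-12)
  expect_equal(fit$indirect, 0.6, tolerance = 1e-12)
})

test_that("orthogonal mediator gives exactly zero indirect effect", {
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  m <- c(1, -1, -1, 1, 1, -1, -1, 1)    # cov(x, m) = 0 by construction
  set.seed(3); y <- rnorm(8)
  fit <- fit_mediation(x, m, y)
  expect_equal(fit$a, 0, tolerance = 1e-14)
  expect_equal(fit$indirect, 0, tolerance = 1e-14)
})

test_that("c = c' + a*b exactly under shared covariates", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 50
    x <- rnorm(n); m <- 0.5 * x + rnorm(n)
    y <- 0.3 * x + 0.8 * m + rnorm(n)
    C <- if (seed %% 2) data.frame(age = rnorm(n),
                                   g = factor(sample(letters[1:3], n,
                                                     TRUE)))
         else NULL
    fit <- fit_mediation(x, m, y, C)
    expect_lt(abs(fit$c - (fit$c_prime + fit$indirect)), 1e-10)
  }
  expect_error(fit_mediation(rep(1, 20), rnorm(20), rnorm(20)), "constant")
  expect_error(fit_mediation(1:20, 2 * (1:20), rnorm(20)), "collinear")
})

test_that("Sobel closed form, degenerate inputs and variants", {
  s <- sobel_test(a = 1, se_a = 0.5, b = 1, se_b = 0.5)
  expect_equal(s$z, 1 / sqrt(0.5), tolerance = 1e-12)   # 1.4142
  expect_equal(s$p, 2 * pnorm(-1 / sqrt(0.5)), tolerance = 1e-12)

  s0 <- sobel_test(a = 0, se_a = 0.5, b = 2, se_b = 0.1)
  expect_equal(s0$z, 0); expect_equal(s0$p, 1)
  expect_error(sobel_test(a = 1, se_a = 0, b = 1, se_b = 0), "zero")
  s2 <- sobel_test(a = 1, se_a = 0.5, b = 1, se_b = 0.5,
                   second_order = TRUE)
  expect_equal(s2$z, 1 / sqrt(0.5625), tolerance = 1e-12)
  # fit-based interface agrees with the explicit one
  set.seed(8)
  x <- rnorm(40); m <- 0.5 * x + rnorm(40); y <- m + rnorm(40)
  fit <- fit_mediation(x, m, y)
  expect_equal(sobel_test(fit)$z,
               sobel_test(fit$a, fit$se_a, fit$b, fit$se_b)$z)
})

test_that("bootstrap is seeded, degenerate-aware and exact when noiseless", {
  set.seed(12)
  x <- rnorm(30); m <- 0.6 * x + rnorm(30); y <- 0.5 * m + rnorm(30)
  b1 <- bootstrap_indirect(x, m, y, n_boot = 200, seed = 5)
  b2 <- bootstrap_indirect(x, m, y, n_boot = 200, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_false(identical(
    b1$ci, bootstrap_indirect(x, m, y, n_boot = 200, seed = 6)$ci))
  expect_true(b1$ci[1] <= b1$indirect && b1$indirect <= b1$ci[2])

  # (near-)perfectly mediated: an exactly linear M is collinear with X in
  # the outcome model (and errors), so jitter M infinitesimally; the CI
  # then collapses onto the true indirect effect 2 * 3 = 6
  set.seed(99)
  xx <- as.numeric(1:20); mm <- 2 * xx + rnorm(20, 0, 1e-3); yy <- 3 * mm
  expect_error(bootstrap_indirect(xx, 2 * xx, 3 * xx, n_boot = 10,
                                  seed = 1), "collinear")
  bz <- bootstrap_indirect(xx, mm, yy, n_boot = 50, seed = 1)
  expect_equal(bz$ci, c(6, 6), tolerance = 1e-2)
  expect_lt(bz$boot_se, 1e-2)

  # almost-always-constant X forces the >10%-redraw error
  x_deg <- c(rep(0, 19), 1)
  expect_error(bootstrap_indirect(x_deg, rnorm(20), rnorm(20),
                                  n_boot = 50, seed = 2), "degenerate")
  expect_error(bootstrap_indirect(rnorm(5), rnorm(5), rnorm(5)),
               "at least 10")
})

test_that("mediation panel enumerates ROI x outcome with stable seeds", {
  tr <- small_truth(seed = 303)
  gen <- generate_gmv_images(generate_cohort(tr), tr)
  co <- gen$cohort
  rm_ <- as.matrix(co[, c("roi_mean_ROI_A", "roi_mean_ROI_B")])
  colnames(rm_) <- c("ROI_A", "ROI_B")
  panel <- run_mediation_panel(co, rm_, n_boot = 100, seed = 9)
  expect_s3_class(panel, "mediation_panel")
  expect_equal(nrow(panel), 4L)                      # 2 ROIs x 2 outcomes
  expect_identical(panel$roi, rep(c("ROI_A", "ROI_B"), each = 2))

  # per-ROI substreams: results do not depend on panel composition
  solo <- run_mediation_panel(co, rm_[, "ROI_B", drop = FALSE],
                              n_boot = 100, seed = 9)
  a <- solo[solo$outcome == "mmse", -1]
  b <- panel[panel$roi == "ROI_B" & panel$outcome == "mmse", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = 1e-12)

  # listwise deletion with a message
  co2 <- co; co2$mmse[1:3] <- NA
  expect_message(p2 <- run_mediation_panel(co2, rm_, outcomes = "mmse",
                                           n_boot = 50, seed = 9),
                 "dropped")
  expect_equal(unique(p2$n), nrow(co) - 3)
})

test_that("sign conventions: atrophy lowers MMSE and raises ADAS-Cog", {
  tr <- small_truth(seed = 404)
  gen <- generate_gmv_images(generate_cohort(tr), tr)
  co <- gen$cohort
  fit_m <- fit_mediation(co$vrf_score, co$mediator_realized, co$mmse,
                         co["group"])
  fit_a <- fit_mediation(co$vrf_score, co$mediator_realized, co$adas_cog,
                         co["group"])
  expect_lt(fit_m$a, 0)      # risk lowers gray matter
  expect_gt(fit_m$b, 0)      # gray matter supports MMSE
  expect_lt(fit_a$b, 0)      # atrophy raises ADAS-Cog
})
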