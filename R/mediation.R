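#' Three-regression mediation with Sobel test and bootstrap CIs
#'
#' The classic single-mediator decomposition of a total effect into direct
#' and indirect paths, fit by three ordinary-least-squares regressions
#' (intercepts always included; the same optional covariates in all
#' three):
#'
#' \deqn{Y = c X + e_1}
#' \deqn{M = a X + e_2}
#' \deqn{Y = c' X + b M + e_3}
#'
#' Here X is the composite vascular-risk score, M the mean ROI gray-matter
#' volume (cortical atrophy), and Y a cognitive score (MMSE or ADAS-Cog).
#' The indirect effect is `a*b`; with a shared covariate set the exact OLS
#' identity `c = c' + a*b` holds. Significance of `a*b` comes from the
#' delta-method Sobel z and from a percentile bootstrap CI over case
#' (subject) resampling.
#'
#' @name mediation
NULL

# model-matrix coding so factor covariates (e.g. diagnostic group) enter
# as dummy columns; numeric matrices pass through untouched
code_covariates <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  if (is.matrix(covariates) && is.numeric(covariates)) return(covariates)
  cm <- stats::model.matrix(~ ., as.data.frame(covariates))
  cm[, -1, drop = FALSE]
}

ols_fit <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear regressors in mediation model: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "))
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(chol2inv(qr.R(qrX))))
  names(se) <- colnames(X)
  list(beta = beta, se = se, df = df)
}

#' Fit the three mediation regressions
#'
#' @param x independent variable (VRF score), numeric vector.
#' @param m mediator (ROI mean GMV).
#' @param y outcome (cognitive score).
#' @param covariates optional data.frame/matrix used identically in all
#'   three models.
#' @return object of class `mediation_fit` with slopes `a`, `b`, `c`,
#'   `c_prime`, their SEs, `indirect = a*b`, dfs and `n`.
#' @export
fit_mediation <- function(x, m, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  if (sd(x) == 0) stop("X is constant")
  if (sd(m) == 0) stop("M is constant")
  C <- code_covariates(covariates)
  Xc <- cbind(`(Intercept)` = rep(1, n), X = x, C)
  Xm <- cbind(Xc[, 1:2, drop = FALSE], M = m, C)
  colnames(Xm)[1:3] <- c("(Intercept)", "X", "M")
  if (n < ncol(Xm) + 1) stop("too few subjects for the largest model")

  f_c <- ols_fit(Xc, y)      # Y = c X (+ covs)
  f_a <- ols_fit(Xc, m)      # M = a X (+ covs)
  f_b <- ols_fit(Xm, y)      # Y = c' X + b M (+ covs)

  structure(list(
    a = unname(f_a$beta["X"]), se_a = unname(f_a$se["X"]),
    b = unname(f_b$beta["M"]), se_b = unname(f_b$se["M"]),
    c = unname(f_c$beta["X"]), se_c = unname(f_c$se["X"]),
    c_prime = unname(f_b$beta["X"]), se_c_prime = unname(f_b$se["X"]),
    indirect = unname(f_a$beta["X"] * f_b$beta["M"]),
    df = c(total = f_c$df, mediator = f_a$df, full = f_b$df),
    n = n, has_covariates = !is.null(C)),
    class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<mediation_fit n=%d: a=%.4g (SE %.3g), b=%.4g (SE %.3g), ",
    "c=%.4g, c'=%.4g, a*b=%.4g>\n"),
    x$n, x$a, x$se_a, x$b, x$se_b, x$c, x$c_prime, x$indirect))
  invisible(x)
}

#' Sobel test of the indirect effect
#'
#' Delta-method z test: `z = a*b / sqrt(b^2 se_a^2 + a^2 se_b^2)` (first
#' order; the second-order variant adds `se_a^2 se_b^2` under the root),
#' with a two-sided standard-normal p.
#'
#' @param a,se_a,b,se_b path estimates and standard errors (or pass a
#'   `mediation_fit` as `a`).
#' @param second_order use the second-order SE variant (default `FALSE`).
#' @return list with `z` and `p`.
#' @export
sobel_test <- function(a, se_a = NULL, b = NULL, se_b = NULL,
                       second_order = FALSE) {
  if (inherits(a, "mediation_fit")) {
    fit <- a; a <- fit$a; se_a <- fit$se_a; b <- fit$b; se_b <- fit$se_b
  }
  if (any(c(se_a, se_b) < 0)) stop("standard errors must be >= 0")
  v <- b^2 * se_a^2 + a^2 * se_b^2
  if (second_order) v <- v + se_a^2 * se_b^2
  if (v == 0) {
    if (a * b == 0) return(list(z = 0, p = 1))
    stop("Sobel denominator is zero with a nonzero indirect effect")
  }
  z <- (a * b) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Percentile bootstrap CI for the indirect effect
#'
#' Case resampling of subjects with replacement; per replicate the
#' mediator and outcome regressions are refit and `a*b` recorded. The CI
#' is the percentile interval at `ci_level`; `boot_se` is the SD of the
#' replicates; the effect is declared significant when the CI excludes
#' zero. Replicates with constant X or M are redrawn (and counted); more
#' than 10% redraws is an error. Deterministic given `seed`.
#'
#' @inheritParams fit_mediation
#' @param n_boot number of bootstrap samples (>= 1000 for inference).
#' @param seed integer seed.
#' @param ci_level confidence level (default 0.95).
#' @return list: `indirect` (point estimate), `boot_se`, `ci` (length 2),
#'   `significant`, `n_boot`, `seed`, `n_redrawn`, `replicates`.
#' @export
bootstrap_indirect <- function(x, m, y, covariates = NULL, n_boot = 1000,
                               seed = 1, ci_level = 0.95) {
  n <- length(x)
  if (n < 10) stop("need at least 10 subjects for the bootstrap")
  if (n_boot < 1) stop("n_boot must be >= 1")
  # code factor covariates to a numeric matrix once; replicates resample
  # its rows (a resample can then never change the dummy coding)
  C <- code_covariates(covariates)
  point <- fit_mediation(x, m, y, C)$indirect

  ab <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    for (bi in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(x[idx]) > 0 && sd(m[idx]) > 0) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 0.1 * n_boot)
          stop("more than 10% of bootstrap replicates were degenerate")
      }
      fit <- try(fit_mediation(x[idx], m[idx], y[idx],
                               if (is.null(C)) NULL
                               else C[idx, , drop = FALSE]),
                 silent = TRUE)   # rare collinear resample of dummies
      if (inherits(fit, "try-error")) {
        # collinear covariate resample: treat like a degenerate replicate
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 0.1 * n_boot)
          stop("more than 10% of bootstrap replicates were degenerate")
        ab[bi] <- NA_real_
      } else ab[bi] <- fit$indirect
    }
  })
  ab <- ab[!is.na(ab)]
  alpha <- 1 - ci_level
  ci <- unname(quantile(ab, c(alpha / 2, 1 - alpha / 2), type = 7))
  list(indirect = point, boot_se = sd(ab), ci = ci,
       significant = ci[1] > 0 || ci[2] < 0,
       n_boot = n_boot, seed = seed, ci_level = ci_level,
       n_redrawn = n_redrawn, replicates = ab)
}

# small stable string hash for order-independent per-ROI seeds
stable_hash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 1048573L
  as.integer(h)
}

#' Run the mediation panel over ROIs and outcomes
#'
#' One mediation analysis per (ROI x outcome): three-regression fit, Sobel
#' test and bootstrap CI, with a per-ROI seed substream derived from the
#' ROI/outcome names so results do not depend on panel composition or
#' order. Subjects with missing values are dropped listwise (with a
#' message). No cross-ROI multiplicity correction is applied.
#'
#' @param cohort data.frame holding the score column, outcomes and any
#'   covariates.
#' @param roi_means subjects x ROIs matrix from [extract_roi_means()]
#'   (rows aligned with `cohort`).
#' @param outcomes character vector of outcome column names (default MMSE
#'   and ADAS-Cog).
#' @param score column name of the independent variable.
#' @param covariates optional character vector of covariate columns used
#'   in all three regressions.
#' @param n_boot,ci_level bootstrap settings (10,000 samples and 95% CI by
#'   default).
#' @param seed master seed.
#' @return data.frame of class `mediation_panel`, one row per ROI x
#'   outcome, sorted by ROI label: a, b, c, c', a*b, Boot SE, CI bounds,
#'   Sobel z / p, significance decision.
#' @export
run_mediation_panel <- function(cohort, roi_means,
                                outcomes = c("mmse", "adas_cog"),
                                score = "vrf_score",
                                covariates = NULL,
                                n_boot = 10000, seed = 11,
                                ci_level = 0.95) {
  roi_means <- as.matrix(roi_means)
  if (nrow(roi_means) != nrow(cohort))
    stop("roi_means rows must align with cohort rows")
  rois <- sort(colnames(roi_means))
  rows <- list()
  for (roi in rois) {
    for (oc in outcomes) {
      cols <- c(score, oc, covariates)
      keep <- stats::complete.cases(cohort[cols]) & !is.na(roi_means[, roi])
      if (any(!keep))
        message(sum(!keep), " subjects dropped listwise for ", roi,
                " / ", oc)
      x <- cohort[[score]][keep]
      m <- roi_means[keep, roi]
      y <- cohort[[oc]][keep]
      C <- if (is.null(covariates)) NULL
           else cohort[keep, covariates, drop = FALSE]
      fit <- fit_mediation(x, m, y, C)
      sob <- sobel_test(fit)
      bs <- bootstrap_indirect(
        x, m, y, C, n_boot = n_boot,
        seed = (seed + stable_hash(paste(roi, oc))) %% .Machine$integer.max,
        ci_level = ci_level)
      rows[[paste(roi, oc)]] <- data.frame(
        roi = roi, outcome = oc, n = fit$n,
        a = fit$a, se_a = fit$se_a, b = fit$b, se_b = fit$se_b,
        c = fit$c, c_prime = fit$c_prime, indirect = fit$indirect,
        boot_se = bs$boot_se, ci_low = bs$ci[1], ci_high = bs$ci[2],
        sobel_z = sob$z, sobel_p = sob$p, significant = bs$significant)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$roi, out$outcome), ]
  rownames(out) <- NULL
  class(out) <- c("mediation_panel", "data.frame")
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "ci_level") <- ci_level
  out
}
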