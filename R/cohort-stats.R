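#' Cohort-level group statistics
#'
#' Table-1-style comparisons across diagnostic groups (one-way ANOVA for
#' numeric variables, Pearson chi-square for categorical ones, Bonferroni
#' post-hoc pairs) and the partial correlation between the VRF score and
#' cognition after covariate adjustment. All p-values are two-sided.
#'
#' @name cohort-stats
NULL

test_result <- function(test, statistic, df, p, extra = list()) {
  structure(c(list(test = test, statistic = statistic, df = df, p = p),
              extra),
            class = "vrf_test")
}

#' @export
print.vrf_test <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$test, x$statistic, dfs, x$p))
  invisible(x)
}

#' One-way ANOVA from raw values
#'
#' Classical between/within sums-of-squares decomposition;
#' `df = (k - 1, N - k)`.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return a `vrf_test` with fields `statistic` (F), `df`, `p`, plus
#'   `ss_between`, `ss_within`, `group_means`.
#' @export
anova_oneway <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  ns <- tabulate(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(ns < 2L)) stop("every group needs n >= 2")
  k <- nlevels(groups); N <- length(values)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(ns * (gm - grand)^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssw <= 0) {
    if (ssb <= 0) stop("all values identical: F undefined")
    stop("zero within-group variance: F undefined")
  }
  f <- (ssb / df1) / (ssw / df2)
  test_result("one-way ANOVA", f, c(df1, df2),
              pf(f, df1, df2, lower.tail = FALSE),
              list(ss_between = ssb, ss_within = ssw,
                   group_means = gm, group_n = ns))
}

#' One-way ANOVA from per-group summary statistics
#'
#' Reconstructs the ANOVA decomposition from (n, mean, SD) per group:
#' `SSb = sum n_g (mean_g - grand)^2`, `SSw = sum (n_g - 1) SD_g^2`. Agrees
#' exactly with [anova_oneway()] on any raw data having those summaries, so
#' published summary rows can be checked without subject-level data.
#'
#' @param n,means,sds equal-length per-group vectors; all `n >= 2`,
#'   `sds >= 0`.
#' @return a `vrf_test`, as [anova_oneway()].
#' @export
anova_from_summary <- function(n, means, sds) {
  stopifnot(length(n) == length(means), length(n) == length(sds))
  if (length(n) < 2L) stop("need at least 2 groups")
  if (any(n < 2)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("SDs must be >= 0")
  N <- sum(n); k <- length(n)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssw <= 0) stop("zero within-group variance: F undefined")
  f <- (ssb / df1) / (ssw / df2)
  test_result("one-way ANOVA (summary)", f, c(df1, df2),
              pf(f, df1, df2, lower.tail = FALSE),
              list(ss_between = ssb, ss_within = ssw))
}

#' Pearson chi-square test on a contingency table
#'
#' Plain X^2 = sum (O - E)^2 / E with `df = (r - 1)(c - 1)`, no continuity
#' correction (matching SPSS's "Pearson Chi-Square" row).
#'
#' @param counts integer matrix of observed counts.
#' @return a `vrf_test` with the X^2 statistic, df, p and expected counts.
#' @export
chi_square_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2x2 table")
  rs <- rowSums(counts); cs <- colSums(counts); N <- sum(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row/column margin: expected counts undefined")
  E <- outer(rs, cs) / N
  x2 <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  test_result("Pearson chi-square", x2, df,
              pchisq(x2, df, lower.tail = FALSE), list(expected = E))
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' Welch two-sample t tests for each configured pair, judged against the
#' family-corrected threshold `alpha_family / m` where `m` is the number of
#' comparisons (e.g. 0.05 / 3 = 0.0167 for the three comparisons against a
#' reference group in a four-group design).
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param reference if non-`NULL`, compare every other group against this
#'   group only; if `NULL`, all pairs.
#' @param alpha_family family-wise alpha (default 0.05).
#' @return data.frame with one row per pair: group labels, t, df (Welch),
#'   p, corrected threshold, and the significance decision.
#' @export
posthoc_pairwise <- function(values, groups, reference = NULL,
                             alpha_family = 0.05) {
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  pairs <- if (is.null(reference)) {
    utils::combn(lev, 2, simplify = FALSE)
  } else {
    if (!reference %in% lev) stop("reference group not found: ", reference)
    lapply(setdiff(lev, reference), function(g) c(g, reference))
  }
  m <- length(pairs)
  if (m == 0L) stop("no comparisons requested")
  thr <- alpha_family / m
  rows <- lapply(pairs, function(pr) {
    x <- values[groups == pr[1]]; y <- values[groups == pr[2]]
    tt <- stats::t.test(x, y)   # Welch
    data.frame(group1 = pr[1], group2 = pr[2],
               mean1 = mean(x), mean2 = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, threshold = thr,
               significant = tt$p.value < thr)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_family") <- alpha_family
  attr(out, "n_comparisons") <- m
  out
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation between the residuals of `x` and `y` after ordinary
#' least-squares regression of each on the covariates (intercept always
#' included). `df = n - n_covariates - 2`; the t statistic is
#' `r * sqrt(df / (1 - r^2))` with a two-sided p.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame / matrix of numeric covariates (may be
#'   `NULL` for a plain correlation).
#' @return a `vrf_test` with fields `statistic` (r), `df`, `p` and `t`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    C <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    C <- as.matrix(as.data.frame(covariates))
    storage.mode(C) <- "numeric"
    if (nrow(C) != n) stop("covariates must have one row per subject")
  }
  q <- ncol(C)
  if (n <= q + 2) stop("need n > n_covariates + 2")
  X <- cbind(`(Intercept)` = 1, C)
  rx <- lm.fit(X, x)$residuals
  ry <- lm.fit(X, y)$residuals
  # tolerance-based: lm.fit leaves O(eps) residuals on exactly-fit vectors
  near_const <- function(r, orig)
    sd(r) <= 1e-10 * max(1, sd(orig), abs(mean(orig)))
  if (near_const(rx, x) || near_const(ry, y))
    stop("x or y constant after residualization")
  r <- cor(rx, ry)
  df <- n - q - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  test_result("partial correlation", r, df, min(p, 1),
              list(t = tstat, n = n, n_covariates = q))
}

#' Summarize a cohort table the way Table-1 rows are reported
#'
#' Mean ± SD per group for numeric variables, per-group counts for
#' categorical ones, with the matching omnibus test.
#'
#' @param cohort data.frame with a `group` column.
#' @param numeric_vars,categorical_vars character vectors of column names.
#' @return list with `summary` (data.frame) and `tests` (named list of
#'   `vrf_test`).
#' @export
cohort_table1 <- function(cohort,
                          numeric_vars = intersect(
                            c("age", "mmse", "adas_cog", "vrf_score"),
                            names(cohort)),
                          categorical_vars = intersect(
                            c("gender", "apoe4"), names(cohort))) {
  stopifnot("group" %in% names(cohort))
  g <- factor(cohort$group, levels = unique(cohort$group))
  tests <- list(); rows <- list()
  row_df <- function(v, cells, p) {
    out <- data.frame(variable = v, t(unname(cells)), p = p,
                      stringsAsFactors = FALSE)
    names(out) <- c("variable", levels(g), "p")
    out
  }
  for (v in numeric_vars) {
    tst <- anova_oneway(cohort[[v]], g)
    tests[[v]] <- tst
    m <- tapply(cohort[[v]], g, mean); s <- tapply(cohort[[v]], g, sd)
    rows[[v]] <- row_df(v, sprintf("%.1f±%.1f", m, s), tst$p)
  }
  for (v in categorical_vars) {
    tab <- table(g, cohort[[v]])
    tst <- chi_square_counts(tab)
    tests[[v]] <- tst
    rows[[v]] <- row_df(v, apply(tab, 1, paste, collapse = "/"), tst$p)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, tests = tests)
}
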