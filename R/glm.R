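#' Mass-univariate linear models on gray-matter volume images
#'
#' Per-voxel ordinary least squares of GMV on a predictor of interest plus
#' nuisance covariates (the classic voxel-based-morphometry regression
#' `GM_i = b0 + b1*predictor + b2*age + b3*gender + b4*education +
#' b5*APOE4 + noise`), and the voxel-wise ANCOVA F-map comparing the
#' group-dummy full model to the covariate-only reduced model. The voxel
#' loop is vectorized as one QR solve across all in-mask voxels; results
#' are identical to per-voxel OLS.
#'
#' @name voxelwise-glm
NULL

#' Per-voxel statistic map
#'
#' @param data 3D numeric array (`NA` outside the mask).
#' @param mask logical 3D array.
#' @param kind one of "beta", "t", "z", "F", "p".
#' @param df degrees of freedom (one or two numbers).
#' @param voxel_size voxel size in mm.
#' @return an object of class `stat_map` (also a `volume`).
#' @export
stat_map <- function(data, mask, kind, df = NULL, voxel_size = c(2, 2, 2)) {
  stopifnot(identical(dim(data), dim(mask)))
  v <- volume_image(data, voxel_size = voxel_size, id = kind)
  v$mask <- mask
  v$kind <- kind
  v$df <- df
  class(v) <- c("stat_map", "volume")
  v
}

#' @export
print.stat_map <- function(x, ...) {
  rng <- range(x$data[x$mask], finite = TRUE)
  cat(sprintf("<stat_map %s, df = (%s), range [%.3g, %.3g], %d voxels>\n",
              x$kind, paste(format(x$df, digits = 4), collapse = ", "),
              rng[1], rng[2], sum(x$mask)))
  invisible(x)
}

#' Build a design matrix
#'
#' Intercept first, predictor of interest second, covariates after;
#' diagnostic group (if requested) enters as k-1 dummy columns against the
#' first level. Gender and APOE4 are expected pre-coded 0/1. The design is
#' checked for full column rank and the offending columns are named on
#' failure.
#'
#' @param cohort cohort data.frame.
#' @param predictor column name of the predictor of interest (e.g.
#'   `"vrf_score"`, `"mmse"`).
#' @param covariates character vector of covariate column names (default
#'   the four nuisance covariates age, gender, education, APOE4).
#' @param include_group also add group dummy columns (default `FALSE`).
#' @return numeric matrix with column names, attribute
#'   `"predictor_index" = 2`.
#' @export
build_design <- function(cohort, predictor,
                         covariates = c("age", "gender", "education",
                                        "apoe4"),
                         include_group = FALSE) {
  need <- c(predictor, covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("columns missing from cohort: ",
                         paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = rep(1, nrow(cohort)),
             as.matrix(as.data.frame(lapply(cohort[need], as.numeric))))
  colnames(X) <- c("(Intercept)", need)
  if (include_group) {
    g <- factor(cohort$group)
    if (nlevels(g) > 1) {
      D <- sapply(levels(g)[-1], function(l) as.numeric(g == l))
      colnames(D) <- paste0("group", levels(g)[-1])
      X <- cbind(X, D)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  attr(X, "predictor_index") <- 2L
  X
}

# stack a list of volumes/arrays into an n x V matrix over the mask
images_to_matrix <- function(images, mask_data) {
  V <- sum(mask_data)
  out <- vapply(images, function(im) as_volume_data(im)[mask_data],
                numeric(V))
  if (V == 1L) matrix(out, ncol = 1L) else t(out)
}

#' Probability-preserving t-to-z conversion
#'
#' Maps a t statistic with `df` degrees of freedom to the standard-normal
#' deviate with the same two-sided tail probability, restoring the sign.
#' Computed in log-probability space so large statistics do not underflow.
#'
#' @param t numeric vector of t values.
#' @param df residual degrees of freedom.
#' @return numeric vector of z values.
#' @export
t_to_z <- function(t, df) {
  z <- -qnorm(pt(-abs(t), df, log.p = TRUE), log.p = TRUE)
  z[is.infinite(t)] <- t[is.infinite(t)]
  sign(t) * abs(z)
}

#' Fit the voxel-wise GLM
#'
#' Ordinary least squares at every in-mask voxel in one matrix solve.
#' Returns beta, t and z maps for the predictor of interest
#' (`t = beta / SE(beta)`, `df = n - p`; z via [t_to_z()]) and retains the
#' residual matrix for smoothness estimation. Voxels with zero residual
#' variance get `t = +/-Inf` and are flagged in `degenerate_voxels` rather
#' than dropped.
#'
#' @param images list of `volume`s (or 3D arrays), one per subject, in
#'   cohort row order.
#' @param mask logical `volume` or array: voxels to analyze.
#' @param design design matrix from [build_design()].
#' @return object of class `vrf_glm`: `beta`, `t`, `z` (stat_maps), `df`,
#'   `residuals` (n x V matrix), `mask`, `degenerate_voxels`.
#' @export
fit_glm <- function(images, mask, design) {
  mask_data <- as_volume_data(mask) > 0
  voxel_size <- if (inherits(mask, "volume")) mask$voxel_size else c(2, 2, 2)
  n <- length(images); p <- ncol(design)
  if (nrow(design) != n) stop("design rows must match number of images")
  if (n <= p) stop("need more images than design columns")
  pi_ <- attr(design, "predictor_index")
  if (is.null(pi_)) pi_ <- 2L

  Y <- images_to_matrix(images, mask_data)
  if (any(!is.finite(Y))) stop("non-finite image values inside mask")
  qrX <- qr(design)
  B <- qr.coef(qrX, Y)
  res <- Y - design %*% B
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtx_inv[pi_, pi_])
  beta1 <- B[pi_, ]
  # a voxel whose residual variance is zero up to floating-point noise is
  # flagged and given an infinite-t sentinel rather than dropped
  degen <- sigma2 <= .Machine$double.eps^0.8 *
    pmax(colMeans(Y^2), .Machine$double.xmin)
  tval <- ifelse(!degen & se > 0, beta1 / se, sign(beta1) * Inf)
  tval[degen & abs(beta1) < sqrt(.Machine$double.eps)] <- 0
  degenerate <- which(degen)
  zval <- t_to_z(tval, df)

  to_map <- function(v, kind, dfk) {
    a <- array(NA_real_, dim(mask_data)); a[mask_data] <- v
    stat_map(a, mask_data, kind, dfk, voxel_size)
  }
  structure(list(
    beta = to_map(beta1, "beta", df),
    t = to_map(tval, "t", df),
    z = to_map(zval, "z", df),
    df = df, design = design, residuals = res, mask = mask_data,
    voxel_size = voxel_size, degenerate_voxels = degenerate),
    class = "vrf_glm")
}

#' Voxel-wise ANCOVA F-map
#'
#' Partial F test at each voxel comparing the full model (intercept +
#' covariates + group dummies) against the reduced covariate-only model:
#' `F = ((RSS_r - RSS_f) / (k - 1)) / (RSS_f / (n - p_full))`, with
#' `df = (k - 1, n - p_full)`.
#'
#' @param images list of subject volumes.
#' @param mask logical mask volume/array.
#' @param groups group labels (length n, >= 2 levels, each n >= 2).
#' @param covariates data.frame/matrix of nuisance covariates (may be
#'   `NULL`).
#' @return object of class `vrf_ancova`: `F` (stat_map), `df`,
#'   `residuals` (full-model), `mask`.
#' @export
fit_ancova <- function(images, mask, groups, covariates = NULL) {
  mask_data <- as_volume_data(mask) > 0
  voxel_size <- if (inherits(mask, "volume")) mask$voxel_size else c(2, 2, 2)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(tabulate(g) < 2)) stop("every group needs n >= 2")
  n <- length(images)
  if (length(g) != n) stop("groups must match number of images")

  C <- if (is.null(covariates)) NULL else {
    m <- as.matrix(as.data.frame(covariates)); storage.mode(m) <- "numeric"; m
  }
  Xr <- cbind(`(Intercept)` = rep(1, n), C)
  D <- sapply(levels(g)[-1], function(l) as.numeric(g == l))
  Xf <- cbind(Xr, D)
  p_full <- ncol(Xf)
  if (n <= p_full) stop("need n > number of full-model parameters")

  Y <- images_to_matrix(images, mask_data)
  qf <- qr(Xf); qr_ <- qr(Xr)
  res_f <- Y - Xf %*% qr.coef(qf, Y)
  res_r <- Y - Xr %*% qr.coef(qr_, Y)
  rss_f <- colSums(res_f^2); rss_r <- colSums(res_r^2)
  df1 <- nlevels(g) - 1L; df2 <- n - p_full
  fval <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  fval[rss_f == 0] <- ifelse(rss_r[rss_f == 0] > rss_f[rss_f == 0], Inf, 0)

  a <- array(NA_real_, dim(mask_data)); a[mask_data] <- fval
  structure(list(
    F = stat_map(a, mask_data, "F", c(df1, df2), voxel_size),
    df = c(df1, df2), residuals = res_f, mask = mask_data,
    voxel_size = voxel_size),
    class = "vrf_ancova")
}
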