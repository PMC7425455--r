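#' Monte-Carlo cluster-extent thresholding
#'
#' Self-contained AFNI-3dClustSim-style correction: estimate the intrinsic
#' smoothness (FWHM) of the analysis residuals, simulate Gaussian null
#' fields at that smoothness inside the brain mask, tabulate the null
#' distribution of the largest supra-threshold cluster, and keep only
#' clusters of a real statistic map at least as large as the tabulated
#' (1 - alpha) extent.
#'
#' @name cluster-mc
NULL

connectivity_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 `6` = rowSums(abs(g)) == 1,
                 `18` = rowSums(abs(g)) <= 2,
                 `26` = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# connected components of the TRUE voxels of a logical 3D array; returns a
# membership vector aligned with which(supra)
label_components <- function(supra, connectivity = 6L) {
  idx <- which(supra)
  nv <- length(idx)
  if (nv == 0L) return(list(idx = idx, membership = integer(0), n = 0L))
  d <- dim(supra)
  coords <- arrayInd(idx, d)
  rank <- integer(prod(d)); rank[idx] <- seq_len(nv)
  offs <- connectivity_offsets(connectivity)
  # only "positive" offsets: each neighbor pair found once
  offs <- offs[offs[, 1] + 2 * offs[, 2] + 4 * offs[, 3] > 0, , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] +
      (nb[ok, 3] - 1) * d[1] * d[2]
    nb_rank <- rank[nb_lin]
    hit <- nb_rank > 0
    if (any(hit))
      edges[[k]] <- rbind(which(ok)[hit], nb_rank[hit])
  }
  edges <- do.call(cbind, edges)
  if (is.null(edges)) {
    membership <- seq_len(nv)
  } else {
    gr <- igraph::make_graph(edges = as.vector(edges), n = nv,
                             directed = FALSE)
    membership <- igraph::components(gr)$membership
  }
  list(idx = idx, membership = membership, n = max(membership))
}

#' Draw one null z-field at a given smoothness
#'
#' Gaussian white noise smoothed to `fwhm_mm` and standardized within the
#' mask — the same null model the cluster-extent table is built from.
#' Used to validate family-wise error calibration.
#'
#' @param mask logical mask volume/array.
#' @param fwhm_mm smoothness in mm.
#' @param seed integer seed.
#' @return a z `stat_map` (`NA` outside the mask).
#' @export
simulate_null_zmap <- function(mask, fwhm_mm, seed) {
  mask_data <- as_volume_data(mask) > 0
  if (!any(mask_data)) stop("empty mask")
  voxel_size <- if (inherits(mask, "volume")) mask$voxel_size else c(2, 2, 2)
  field <- with_seed(seed,
    smooth_noise_field(dim(mask_data), voxel_size, fwhm_mm, mask_data))
  field[!mask_data] <- NA_real_
  stat_map(field, mask_data, "z", Inf, voxel_size)
}

#' Estimate map smoothness from residual images
#'
#' Gradient method: each residual image is standardized within the mask;
#' for every axis the variance `v` of first differences between in-mask
#' neighbor pairs is pooled across images and converted to
#' `FWHM = d * sqrt(4 ln 2 / v)` (`d` = voxel size along the axis). For
#' unsmoothed white noise `v = 2` and the estimate is `1.18 d`, i.e. about
#' one voxel, as it should be.
#'
#' @param residuals either a `vrf_glm` / `vrf_ancova` fit, a list of 3D
#'   arrays/volumes, or an n x V residual matrix (then `mask` is required
#'   to place values back on the grid).
#' @param mask logical mask volume/array.
#' @return object of class `smoothness`: `fwhm_mm` (per axis), `mean_fwhm_mm`,
#'   `method`.
#' @export
estimate_smoothness <- function(residuals, mask = NULL) {
  if (inherits(residuals, c("vrf_glm", "vrf_ancova"))) {
    mask <- residuals$mask
    voxel_size <- residuals$voxel_size
    res_mat <- residuals$residuals
  } else if (is.matrix(residuals)) {
    if (is.null(mask)) stop("mask required with a residual matrix")
    voxel_size <- if (inherits(mask, "volume")) mask$voxel_size else c(2, 2, 2)
    res_mat <- residuals
  } else {
    if (is.null(mask)) stop("mask required with a list of images")
    voxel_size <- if (inherits(mask, "volume")) mask$voxel_size else c(2, 2, 2)
    res_mat <- images_to_matrix(residuals, as_volume_data(mask) > 0)
  }
  mask_data <- as_volume_data(mask) > 0
  if (nrow(res_mat) < 2) stop("need at least 2 residual images")
  d <- dim(mask_data)
  idx <- which(mask_data)
  coords <- arrayInd(idx, d)
  rank <- integer(prod(d)); rank[idx] <- seq_len(length(idx))

  ss_diff <- numeric(3); n_diff <- numeric(3)
  pair <- vector("list", 3)
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L); off[ax] <- 1L
    nb <- sweep(coords, 2, off, `+`)
    ok <- nb[, ax] <= d[ax]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] +
      (nb[ok, 3] - 1) * d[1] * d[2]
    nb_rank <- rank[nb_lin]
    hit <- nb_rank > 0
    pair[[ax]] <- cbind(which(ok)[hit], nb_rank[hit])
  }
  for (i in seq_len(nrow(res_mat))) {
    v <- res_mat[i, ]
    sdv <- sd(v)
    if (sdv == 0) stop("constant residual image: smoothness undefined")
    v <- (v - mean(v)) / sdv
    for (ax in 1:3) {
      dv <- v[pair[[ax]][, 1]] - v[pair[[ax]][, 2]]
      ss_diff[ax] <- ss_diff[ax] + sum(dv^2)
      n_diff[ax] <- n_diff[ax] + length(dv)
    }
  }
  var_d <- ss_diff / n_diff
  fwhm <- voxel_size * sqrt(4 * log(2) / var_d)
  structure(list(fwhm_mm = fwhm, mean_fwhm_mm = mean(fwhm),
                 method = "gradient-variance"),
            class = "smoothness")
}

#' @export
print.smoothness <- function(x, ...) {
  cat(sprintf("<smoothness: FWHM = %s mm (mean %.2f), method %s>\n",
              paste(sprintf("%.2f", x$fwhm_mm), collapse = "/"),
              x$mean_fwhm_mm, x$method))
  invisible(x)
}

#' Simulate the null distribution of maximum cluster extent
#'
#' Per iteration: draw a Gaussian white-noise field, smooth it to
#' `fwhm_mm`, standardize within the mask (so the voxel-wise threshold is
#' exact under the null), threshold, and record the largest connected
#' cluster. The extent threshold for each `(voxel_p, alpha)` pair is the
#' ceiling of the `(1 - alpha)` empirical quantile of the per-iteration
#' maxima (at least 1 voxel). Deterministic given `seed`.
#'
#' @param mask logical mask volume/array.
#' @param fwhm_mm assumed smoothness of the noise (mm).
#' @param voxel_p vector of voxel-wise p thresholds in (0, 1).
#' @param alpha vector of cluster-level alphas in (0, 1].
#' @param n_iter number of Monte-Carlo iterations (>= 1000 recommended).
#' @param seed integer seed.
#' @param connectivity 6, 18 or 26.
#' @param two_tailed threshold on `|z|` (default) or on `z` only.
#' @return object of class `cluster_threshold_table`: data.frame `table`
#'   (voxel_p, alpha, k_voxels, k_mm3) plus simulation metadata and the
#'   raw `max_sizes` matrix (n_iter x length(voxel_p)).
#' @export
simulate_cluster_null <- function(mask, fwhm_mm, voxel_p = 0.01,
                                  alpha = 0.05, n_iter = 1000,
                                  seed = 1, connectivity = 6,
                                  two_tailed = TRUE) {
  mask_data <- as_volume_data(mask) > 0
  if (!any(mask_data)) stop("empty mask")
  if (any(voxel_p <= 0 | voxel_p >= 1)) stop("voxel_p must be in (0,1)")
  if (any(alpha <= 0 | alpha > 1)) stop("alpha must be in (0,1]")
  voxel_size <- if (inherits(mask, "volume")) mask$voxel_size else c(2, 2, 2)
  d <- dim(mask_data)
  zthr <- if (two_tailed) qnorm(1 - voxel_p / 2) else qnorm(1 - voxel_p)

  max_sizes <- matrix(0L, n_iter, length(voxel_p))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      field <- smooth_noise_field(d, voxel_size, fwhm_mm, mask_data)
      vals <- if (two_tailed) abs(field) else field
      vals[!mask_data] <- -Inf
      for (j in seq_along(voxel_p)) {
        supra <- array(vals >= zthr[j], dim = d)
        if (!any(supra)) next
        lab <- label_components(supra, connectivity)
        max_sizes[it, j] <- max(tabulate(lab$membership))
      }
    }
  })

  grid <- expand.grid(voxel_p = voxel_p, alpha = alpha,
                      KEEP.OUT.ATTRS = FALSE)
  grid$k_voxels <- mapply(function(p, a) {
    ms <- max_sizes[, match(p, voxel_p)]
    max(1L, as.integer(ceiling(quantile(ms, 1 - a, type = 1, names = FALSE))))
  }, grid$voxel_p, grid$alpha)
  grid$k_mm3 <- as.numeric(grid$k_voxels * voxel_volume_mm3(voxel_size))
  structure(list(table = grid, n_iter = n_iter, seed = seed,
                 connectivity = connectivity, fwhm_mm = fwhm_mm,
                 two_tailed = two_tailed, voxel_size = voxel_size,
                 max_sizes = max_sizes, voxel_p_levels = voxel_p),
            class = "cluster_threshold_table")
}

#' @export
print.cluster_threshold_table <- function(x, ...) {
  cat(sprintf(
    "<cluster_threshold_table: fwhm %.2g mm, %d iters, conn %d, %s>\n",
    x$fwhm_mm, x$n_iter, x$connectivity,
    if (x$two_tailed) "two-tailed" else "one-tailed"))
  print(x$table)
  invisible(x)
}

#' Write / read a cluster-threshold table as JSON
#' @param x a `cluster_threshold_table`.
#' @param path JSON file path.
#' @return `path` (write) or the table object (read). The Monte-Carlo
#'   `max_sizes` sample is not serialized.
#' @export
write_cluster_table <- function(x, path) {
  obj <- unclass(x)
  obj$max_sizes <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$table <- as.data.frame(obj$table)
  obj$table$k_voxels <- as.integer(obj$table$k_voxels)
  obj$table$k_mm3 <- as.numeric(obj$table$k_mm3)
  structure(obj, class = "cluster_threshold_table")
}

#' Extract supra-threshold clusters from a statistic map
#'
#' Connected components of voxels passing the voxel threshold under the
#' stated connectivity. Sizes are reported in voxels and mm^3; each
#' cluster carries its peak value, peak voxel location and center of mass
#' (unweighted centroid, voxel coordinates).
#'
#' @param map a `stat_map` (or `volume`/array with `mask` supplied).
#' @param threshold voxel threshold on the statistic.
#' @param mask optional logical mask (defaults to the map's own mask).
#' @param connectivity 6, 18 or 26.
#' @param direction `"two_sided"` (cluster on `|value| >= threshold`,
#'   default), `"greater"` or `"less"`.
#' @return object of class `cluster_set`: data.frame `clusters`, integer
#'   `labels` array, the threshold and connectivity used.
#' @export
extract_clusters <- function(map, threshold, mask = NULL, connectivity = 6,
                             direction = c("two_sided", "greater", "less")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite")
  dat <- as_volume_data(map)
  if (is.null(mask)) mask <- if (!is.null(map$mask)) map$mask else !is.na(dat)
  mask_data <- as_volume_data(mask) > 0
  voxel_size <- if (inherits(map, "volume")) map$voxel_size
                else if (inherits(mask, "volume")) mask$voxel_size
                else c(2, 2, 2)
  d <- dim(dat)
  crit <- switch(direction,
                 two_sided = abs(dat) >= threshold,
                 greater = dat >= threshold,
                 less = dat <= -abs(threshold))
  crit[is.na(crit)] <- FALSE
  supra <- array(crit & mask_data, dim = d)
  lab <- label_components(supra, connectivity)
  labels <- array(0L, dim = d)
  clusters <- data.frame(label = integer(0), n_voxels = integer(0),
                         mm3 = numeric(0), peak_value = numeric(0),
                         peak_x = integer(0), peak_y = integer(0),
                         peak_z = integer(0), com_x = numeric(0),
                         com_y = numeric(0), com_z = numeric(0))
  if (lab$n > 0L) {
    labels[lab$idx] <- lab$membership
    coords <- arrayInd(lab$idx, d)
    vals <- dat[lab$idx]
    rows <- lapply(seq_len(lab$n), function(k) {
      sel <- lab$membership == k
      v <- vals[sel]; cc <- coords[sel, , drop = FALSE]
      pk <- which.max(abs(v))
      data.frame(label = k, n_voxels = sum(sel),
                 mm3 = sum(sel) * voxel_volume_mm3(voxel_size),
                 peak_value = v[pk],
                 peak_x = cc[pk, 1], peak_y = cc[pk, 2], peak_z = cc[pk, 3],
                 com_x = mean(cc[, 1]), com_y = mean(cc[, 2]),
                 com_z = mean(cc[, 3]))
    })
    clusters <- do.call(rbind, rows)
    clusters <- clusters[order(-clusters$n_voxels), ]
    rownames(clusters) <- NULL
  }
  structure(list(clusters = clusters, labels = labels,
                 threshold = threshold, connectivity = connectivity,
                 direction = direction, voxel_size = voxel_size),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set: %d clusters at |stat| >= %.3g (conn %d)>\n",
              nrow(x$clusters), x$threshold, x$connectivity))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Apply Monte-Carlo cluster-extent correction to a z map
#'
#' Thresholds the map at the voxel-wise p (two-tailed `|z|` by default,
#' matching the table's setting), then keeps only clusters whose extent is
#' at least the tabulated minimum for `(voxel_p, alpha)` (`>=` semantics: a
#' cluster exactly at threshold survives).
#'
#' @param map a z `stat_map`.
#' @param table a [simulate_cluster_null()] result.
#' @param voxel_p,alpha the entry of `table` to use.
#' @return list: `mask` (binary `volume` of surviving voxels), `clusters`
#'   (surviving `cluster_set` rows), `k_voxels` (extent threshold used),
#'   `z_threshold`.
#' @export
apply_cluster_correction <- function(map, table, voxel_p, alpha) {
  stopifnot(inherits(table, "cluster_threshold_table"))
  row <- which(abs(table$table$voxel_p - voxel_p) < 1e-12 &
               abs(table$table$alpha - alpha) < 1e-12)
  if (length(row) != 1L)
    stop(sprintf("no entry for voxel_p = %g, alpha = %g in the table",
                 voxel_p, alpha))
  k <- table$table$k_voxels[row]
  zthr <- if (table$two_tailed) qnorm(1 - voxel_p / 2) else qnorm(1 - voxel_p)
  cs <- extract_clusters(map, zthr, connectivity = table$connectivity,
                         direction = if (table$two_tailed) "two_sided"
                                     else "greater")
  keep <- cs$clusters$n_voxels >= k
  surv_labels <- cs$clusters$label[keep]
  bin <- array(cs$labels %in% surv_labels & cs$labels > 0L,
               dim = dim(cs$labels))
  cs$clusters <- cs$clusters[keep, , drop = FALSE]
  cs$labels[!bin] <- 0L
  list(mask = volume_image(bin, voxel_size = cs$voxel_size,
                           id = "corrected"),
       clusters = cs, k_voxels = k, z_threshold = zthr)
}
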