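#' 3D volume images
#'
#' A `volume` is the package's in-memory form of a 3D scalar grid: a numeric
#' array plus voxel dimensions in mm and a world-space origin offset. It is
#' used for gray-matter volume maps, brain masks and statistic maps alike.
#'
#' @param data numeric or logical 3D array.
#' @param voxel_size length-3 positive numeric, voxel edge lengths in mm.
#' @param origin length-3 numeric, world coordinate of voxel (1,1,1) in mm.
#' @param id optional subject or map identifier.
#' @return an object of class `volume`.
#' @export
volume_image <- function(data, voxel_size = c(2, 2, 2), origin = c(0, 0, 0),
                         id = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive numbers (mm)")
  structure(
    list(data = data, voxel_size = voxel_size,
         origin = as.numeric(origin), id = id),
    class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume %dx%dx%d, voxel %s mm%s>\n", d[1], d[2], d[3],
              paste(format(x$voxel_size), collapse = "x"),
              if (is.null(x$id)) "" else paste0(", id=", x$id)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Volume of one voxel in cubic millimetres
#' @param x a `volume` or a length-3 voxel-size vector.
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(x) {
  vs <- if (inherits(x, "volume")) x$voxel_size else as.numeric(x)
  prod(vs)
}

as_volume_data <- function(x) {
  if (inherits(x, "volume")) x$data else x
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  da <- dim(as_volume_data(a)); db <- dim(as_volume_data(b))
  if (!identical(da, db))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

# FWHM of a Gaussian <-> its standard deviation
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))   # 1/2.3548

#' Separable Gaussian smoothing of a 3D array
#'
#' Smooths along each axis with a discrete Gaussian kernel whose standard
#' deviation is `fwhm_mm * 0.4247 / voxel_size` voxels. Kernel rows are
#' renormalized to sum to one, so edges are handled by renormalized weighted
#' averaging (no wrap-around). Implemented as three kernel-matrix products,
#' which is fast for the grid sizes used here.
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm scalar or length-3 FWHM in mm; 0 returns `arr` unchanged.
#' @param voxel_size length-3 voxel size in mm.
#' @return smoothed array, same dimensions.
#' @export
gaussian_smooth <- function(arr, fwhm_mm, voxel_size = c(2, 2, 2)) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(fwhm_mm < 0)) stop("fwhm_mm must be >= 0")
  if (all(fwhm_mm == 0)) return(arr)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    if (fwhm_mm[ax] == 0) next
    sigma_vox <- fwhm_mm[ax] * FWHM_TO_SIGMA / voxel_size[ax]
    K <- gaussian_kernel_matrix(d[ax], sigma_vox)
    out <- apply_along_axis(out, ax, K)
  }
  out
}

# n x n matrix K with K[i, j] = normalized Gaussian weight of source j for
# target i; truncated at 4 sigma.
gaussian_kernel_matrix <- function(n, sigma_vox) {
  idx <- seq_len(n)
  D <- outer(idx, idx, function(i, j) (i - j))
  K <- exp(-(D^2) / (2 * sigma_vox^2))
  K[abs(D) > max(4 * sigma_vox, 1)] <- 0
  K / rowSums(K)
}

# multiply kernel matrix K (n_ax x n_ax) along axis `ax` of 3D array
apply_along_axis <- function(arr, ax, K) {
  d <- dim(arr)
  if (ax == 1L) {
    m <- K %*% matrix(arr, nrow = d[1])
    array(m, dim = d)
  } else if (ax == 2L) {
    perm <- aperm(arr, c(2, 1, 3))
    m <- K %*% matrix(perm, nrow = d[2])
    aperm(array(m, dim = d[c(2, 1, 3)]), c(2, 1, 3))
  } else {
    perm <- aperm(arr, c(3, 1, 2))
    m <- K %*% matrix(perm, nrow = d[3])
    aperm(array(m, dim = d[c(3, 1, 2)]), c(2, 3, 1))
  }
}

#' Spherical brain mask on a cubic grid
#'
#' Convenience mask generator used by the synthetic module and tests: a
#' centred sphere, the stand-in for an MNI brain mask at desk scale.
#'
#' @param grid_shape length-3 integer grid dimensions.
#' @param radius_vox sphere radius in voxels (default 45% of smallest axis).
#' @param voxel_size voxel size in mm.
#' @return a logical `volume` mask.
#' @export
spherical_mask <- function(grid_shape = c(32, 32, 32), radius_vox = NULL,
                           voxel_size = c(2, 2, 2)) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(radius_vox)) radius_vox <- 0.45 * min(grid_shape)
  ctr <- (grid_shape + 1) / 2
  ix <- seq_len(grid_shape[1]); iy <- seq_len(grid_shape[2])
  iz <- seq_len(grid_shape[3])
  dx2 <- (ix - ctr[1])^2
  dy2 <- (iy - ctr[2])^2
  dz2 <- (iz - ctr[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  volume_image(array(r2 <= radius_vox^2, dim = grid_shape),
               voxel_size = voxel_size, id = "brain_mask")
}

#' Rectangular (box) ROI mask
#'
#' @param grid_shape length-3 grid dimensions.
#' @param lo,hi length-3 inclusive 1-based voxel index bounds.
#' @param voxel_size voxel size in mm.
#' @return a logical `volume` mask.
#' @export
box_mask <- function(grid_shape, lo, hi, voxel_size = c(2, 2, 2)) {
  grid_shape <- as.integer(grid_shape)
  if (any(lo < 1) || any(hi > grid_shape) || any(lo > hi))
    stop("box bounds fall outside the grid")
  m <- array(FALSE, dim = grid_shape)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  volume_image(m, voxel_size = voxel_size)
}
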