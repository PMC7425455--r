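#' Conjunction of corrected maps and ROI extraction
#'
#' The overlap ("conjunction") of two cluster-corrected binary maps — the
#' voxels where, e.g., both the VRF effect and a cognition effect on GMV
#' survive correction — defines the regions of interest whose mean GMV is
#' the mediator fed to the mediation stage.
#'
#' @name conjunction-roi
NULL

#' Voxel-wise conjunction (logical AND) of two binary maps
#'
#' @param a,b binary `volume`s or logical/0-1 arrays on the same grid.
#' @return logical `volume`.
#' @export
conjunction <- function(a, b) {
  stopifnot_same_grid(a, b, "conjunction inputs")
  da <- as_volume_data(a) > 0
  db <- as_volume_data(b) > 0
  voxel_size <- if (inherits(a, "volume")) a$voxel_size
                else if (inherits(b, "volume")) b$voxel_size else c(2, 2, 2)
  volume_image(array(da & db, dim = dim(da)), voxel_size = voxel_size,
               id = "conjunction")
}

#' Split a conjunction map into labeled ROIs
#'
#' Connected components become named ROIs (`ROI_001`, `ROI_002`, ...,
#' ordered by descending size); components smaller than `min_size` voxels
#' are dropped. Pretty anatomical names may be substituted afterwards via
#' the `names` argument of downstream functions — no atlas is bundled.
#'
#' @param map binary `volume`/array.
#' @param connectivity 6, 18 or 26.
#' @param min_size minimum component size in voxels.
#' @return object of class `roi_set`: `masks` (named list of logical
#'   arrays), `labels` (integer array), `names`, `sizes`, `voxel_size`.
#' @export
split_rois <- function(map, connectivity = 6, min_size = 1) {
  dat <- as_volume_data(map) > 0
  voxel_size <- if (inherits(map, "volume")) map$voxel_size else c(2, 2, 2)
  d <- dim(dat)
  lab <- label_components(array(dat, dim = d), connectivity)
  labels <- array(0L, dim = d)
  masks <- list(); sizes <- integer(0)
  if (lab$n > 0L) {
    sz <- tabulate(lab$membership)
    keep <- which(sz >= min_size)
    keep <- keep[order(-sz[keep])]
    for (j in seq_along(keep)) {
      nm <- sprintf("ROI_%03d", j)
      m <- array(FALSE, dim = d)
      m[lab$idx[lab$membership == keep[j]]] <- TRUE
      masks[[nm]] <- m
      labels[m] <- j
      sizes[nm] <- sz[keep[j]]
    }
  }
  structure(list(masks = masks, labels = labels, names = names(masks),
                 sizes = sizes, voxel_size = voxel_size),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set: %d ROIs%s>\n", length(x$masks),
              if (length(x$masks))
                paste0(" (", paste(sprintf("%s:%d", x$names, x$sizes),
                                   collapse = ", "), " voxels)")
              else ""))
  invisible(x)
}

#' Mean image value per subject and ROI
#'
#' The subjects-by-ROIs matrix of mean GMV inside each ROI mask — the
#' mediator matrix for [run_mediation_panel()].
#'
#' @param images list of subject `volume`s/arrays on the ROI grid.
#' @param roiset a [split_rois()] result (or named list of logical masks).
#' @return numeric matrix, rows = subjects, columns = ROIs.
#' @export
extract_roi_means <- function(images, roiset) {
  masks <- if (inherits(roiset, "roi_set")) roiset$masks else roiset
  if (length(masks) == 0L) stop("empty ROI set")
  for (nm in names(masks))
    if (!any(as_volume_data(masks[[nm]]))) stop("empty ROI: ", nm)
  out <- matrix(NA_real_, length(images), length(masks),
                dimnames = list(NULL, names(masks)))
  for (i in seq_along(images)) {
    dat <- as_volume_data(images[[i]])
    stopifnot_same_grid(dat, masks[[1]], "image and ROI masks")
    for (j in seq_along(masks))
      out[i, j] <- mean(dat[as_volume_data(masks[[j]])])
  }
  out
}

#' Fraction of a ground-truth ROI recovered by a map
#'
#' Sensitivity of a detected (e.g. conjunction) map against an embedded
#' truth mask: `|detected AND truth| / |truth|`.
#'
#' @param detected,truth binary `volume`s/arrays on one grid.
#' @return scalar in \[0, 1\].
#' @export
roi_recovery <- function(detected, truth) {
  stopifnot_same_grid(detected, truth, "recovery inputs")
  dt <- as_volume_data(detected) > 0
  tr <- as_volume_data(truth) > 0
  if (!any(tr)) stop("empty truth mask")
  sum(dt & tr) / sum(tr)
}
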