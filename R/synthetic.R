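#' Synthetic cohorts and gray-matter volume images with known ground truth
#'
#' The generator emulates the *outputs* of a voxel-based morphometry
#' pipeline — modulated gray-matter volume (GMV) maps resampled to 2 mm
#' isotropic voxels and smoothed to 6 mm FWHM — for a four-group
#' Alzheimer's-spectrum cohort (CN / EMCI / LMCI / AD), with an explicit,
#' recorded mediation structure: the composite vascular-risk score lowers
#' ROI gray matter (`beta_vrf_gmv` per score unit), ROI gray matter drives
#' cognition (`beta_gmv_cog`), and a direct risk-to-cognition path
#' (`beta_direct`) remains. Everything is additive, linear and Gaussian, so
#' parameter recovery by the downstream linear analyses is well defined.
#'
#' Randomness is governed by one integer seed with fixed per-stage
#' substreams (`seed + 1` for the cohort, `seed + 2` for the images), so
#' identical seeds give byte-identical outputs.
#'
#' @name synthetic-data
NULL

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

GROUPS <- c("CN", "EMCI", "LMCI", "AD")

default_prevalence <- function() {
  # per-group Bernoulli prevalences for the six factors, chosen once so the
  # unit-weight composite means are close to 1.1 / 1.4 / 1.4 / 2.1
  m <- rbind(
    CN   = c(diabetes = 0.10, hypertension = 0.45, smoking = 0.05,
             depression = 0.15, low_education = 0.10, obesity = 0.25),
    EMCI = c(0.15, 0.50, 0.08, 0.25, 0.12, 0.30),
    LMCI = c(0.15, 0.50, 0.08, 0.25, 0.12, 0.30),
    AD   = c(0.25, 0.65, 0.15, 0.40, 0.20, 0.45))
  colnames(m) <- VRF_FACTORS
  m
}

#' Ground truth for a synthetic dataset
#'
#' Collects every generator parameter plus the implied true indirect
#' effects (recorded here, never re-derived, so recovery tests have a fixed
#' target). Defaults state the emulated world: group sizes 69/52/41/30, a
#' 32x32x32 grid of 2 mm voxels, 6 mm smoothing, two box ROIs inside a
#' spherical brain mask, and effect sizes at which the full pipeline has
#' realistic (not saturated) signal-to-noise.
#'
#' @param group_sizes named integer vector, subjects per group (all >= 2).
#' @param grid_shape length-3 grid dimensions.
#' @param voxel_size voxel edge lengths in mm.
#' @param roi_masks named list of logical `volume` masks; `NULL` for the
#'   two default box ROIs.
#' @param beta_vrf_gmv effect of the composite score on ROI GMV, in GMV
#'   units per score unit (negative = atrophy).
#' @param beta_gmv_cog named length-2 vector (`mmse`, `adas_cog`): effect
#'   of ROI GMV on each cognitive score, in score points per GMV unit.
#' @param beta_direct named length-2 vector: direct score-to-cognition
#'   effect in points per score unit.
#' @param group_atrophy additive group-level GMV offset (GMV units), one
#'   per group.
#' @param subject_sd_gmv SD of the per-subject anatomical deviation of ROI
#'   gray matter (GMV units) beyond what group and risk score explain; this
#'   is the variation that identifies the mediator-to-cognition path.
#' @param noise_sd_image per-voxel SD of the smoothed image noise field.
#' @param noise_sd_cog named length-2 vector of cognition noise SDs.
#' @param vrf_prevalence groups x factors matrix of Bernoulli
#'   probabilities in \[0, 1\].
#' @param smoothing_fwhm_mm smoothing FWHM of the noise field, mm (>= 0).
#' @param seed integer master seed.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(group_sizes = c(CN = 69, EMCI = 52, LMCI = 41,
                                         AD = 30),
                         grid_shape = c(32, 32, 32),
                         voxel_size = c(2, 2, 2),
                         roi_masks = NULL,
                         beta_vrf_gmv = -0.03,
                         beta_gmv_cog = c(mmse = 30, adas_cog = -90),
                         beta_direct = c(mmse = -0.2, adas_cog = 0.6),
                         group_atrophy = c(CN = 0, EMCI = -0.01,
                                           LMCI = -0.02, AD = -0.05),
                         subject_sd_gmv = 0.05,
                         noise_sd_image = 0.02,
                         noise_sd_cog = c(mmse = 1.0, adas_cog = 4.0),
                         vrf_prevalence = default_prevalence(),
                         smoothing_fwhm_mm = 6,
                         seed = 20200729) {
  group_sizes <- as.integer(group_sizes)
  names(group_sizes) <- GROUPS
  if (any(group_sizes < 2)) stop("all group sizes must be >= 2")
  if (any(vrf_prevalence < 0 | vrf_prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  if (smoothing_fwhm_mm < 0) stop("smoothing_fwhm_mm must be >= 0")
  grid_shape <- as.integer(grid_shape)

  mask <- spherical_mask(grid_shape, voxel_size = voxel_size)
  if (is.null(roi_masks)) {
    # two boxes straddling the centre along x, well inside the sphere
    sz <- pmax(round(grid_shape / 6), 2L)
    ctr <- (grid_shape + 1) / 2
    off <- max(round(grid_shape[1] / 8), sz[1] %/% 2 + 1L)
    loA <- round(ctr - c(off, 0, 0) - (sz - 1) / 2)
    loB <- round(ctr + c(off, 0, 0) - (sz - 1) / 2)
    roi_masks <- list(
      ROI_A = box_mask(grid_shape, loA, loA + sz - 1L, voxel_size),
      ROI_B = box_mask(grid_shape, loB, loB + sz - 1L, voxel_size))
  }
  if (is.null(names(roi_masks)) || anyDuplicated(names(roi_masks)))
    stop("roi_masks must have unique names")
  occupied <- array(FALSE, grid_shape)
  for (nm in names(roi_masks)) {
    rm_ <- as_volume_data(roi_masks[[nm]])
    if (!identical(dim(rm_), dim(mask$data)))
      stop("ROI mask ", nm, " does not match the grid")
    if (!any(rm_)) stop("ROI mask ", nm, " is empty")
    if (any(rm_ & !mask$data))
      stop("ROI mask ", nm, " extends outside the brain mask")
    if (any(rm_ & occupied)) stop("ROI masks overlap at ", nm)
    occupied <- occupied | rm_
  }

  truth <- structure(list(
    group_sizes = group_sizes, grid_shape = grid_shape,
    voxel_size = rep_len(as.numeric(voxel_size), 3),
    brain_mask = mask, roi_masks = roi_masks, roi_union = occupied,
    beta_vrf_gmv = beta_vrf_gmv, beta_gmv_cog = beta_gmv_cog,
    beta_direct = beta_direct, group_atrophy = group_atrophy,
    subject_sd_gmv = subject_sd_gmv,
    noise_sd_image = noise_sd_image, noise_sd_cog = noise_sd_cog,
    vrf_prevalence = vrf_prevalence,
    smoothing_fwhm_mm = smoothing_fwhm_mm, seed = as.integer(seed)),
    class = "ground_truth")
  # recorded, not re-derived: the implied true indirect effects
  truth$true_indirect <- beta_vrf_gmv * beta_gmv_cog
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0(
    "<ground_truth: n = %s, grid %s @ %g mm, %d ROIs, ",
    "beta_vrf_gmv = %g, fwhm = %g mm, seed = %d>\n"),
    paste(x$group_sizes, collapse = "/"),
    paste(x$grid_shape, collapse = "x"), x$voxel_size[1],
    length(x$roi_masks), x$beta_vrf_gmv, x$smoothing_fwhm_mm, x$seed))
  invisible(x)
}

# smooth radial baseline gray-matter template: denser centrally, thinning
# toward the rim, zero outside the brain mask
gm_template <- function(truth) {
  d <- truth$grid_shape
  ctr <- (d + 1) / 2
  r2 <- outer(outer((seq_len(d[1]) - ctr[1])^2,
                    (seq_len(d[2]) - ctr[2])^2, `+`),
              (seq_len(d[3]) - ctr[3])^2, `+`)
  R2 <- max(r2[truth$brain_mask$data])
  tpl <- (0.75 - 0.30 * r2 / R2)
  tpl[!truth$brain_mask$data] <- 0
  array(tpl, dim = d)
}

# expected (noiseless) mediator: mean over the ROI union of the noiseless
# image for a subject with given group and score
expected_mediator <- function(truth, group, score) {
  tpl <- gm_template(truth)
  base <- mean(tpl[truth$roi_union])
  base + truth$group_atrophy[group] + truth$beta_vrf_gmv * score
}

#' Generate a synthetic cohort table
#'
#' One row per subject: demographics (age, gender with 1 = female, APOE
#' epsilon-4 carrier status, years of education), the six binary VRFs drawn
#' from the group-specific prevalences, the unit-weight composite score,
#' the noiseless ("expected") mediator value, and MMSE / ADAS-Cog built as
#' linear functions of that mediator plus the direct risk effect plus
#' Gaussian noise. MMSE is clipped to \[0, 30\] (a real ceiling the
#' generator reproduces; see the vignette). Deterministic given
#' `truth$seed`.
#'
#' @param truth a [ground_truth()] object.
#' @return a data.frame cohort table.
#' @export
generate_cohort <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  n_g <- truth$group_sizes
  if (any(n_g <= 0)) stop("non-positive group size")
  N <- sum(n_g)
  group <- factor(rep(GROUPS, times = n_g), levels = GROUPS)

  # group-level demographic anchors (age means/SDs and carrier rates follow
  # typical Alzheimer's-spectrum cohort tables)
  age_mean <- c(CN = 73.6, EMCI = 71.2, LMCI = 71.5, AD = 73.1)
  p_female <- c(CN = 0.58, EMCI = 0.60, LMCI = 0.41, AD = 0.50)
  p_apoe4 <- c(CN = 0.30, EMCI = 0.50, LMCI = 0.41, AD = 0.73)

  with_seed(truth$seed + 1L, {
    age <- round(rnorm(N, age_mean[group], 7), 1)
    gender <- rbinom(N, 1, p_female[group])
    apoe4 <- rbinom(N, 1, p_apoe4[group])
    education <- round(pmin(pmax(rnorm(N, 16, 2.7), 6), 20))
    ind <- sapply(VRF_FACTORS, function(f)
      rbinom(N, 1, truth$vrf_prevalence[as.integer(group), f]))
    ind <- as.data.frame(ind)
    score <- vrf_composite(ind)

    med_true <- expected_mediator(truth, group, score) +
      rnorm(N, 0, truth$subject_sd_gmv)
    base_med <- expected_mediator(truth, factor("CN", levels = GROUPS), 0)
    mmse <- 28.2 + truth$beta_gmv_cog[["mmse"]] * (med_true - base_med) +
      truth$beta_direct[["mmse"]] * score +
      rnorm(N, 0, truth$noise_sd_cog[["mmse"]])
    mmse <- pmin(pmax(round(mmse, 1), 0), 30)
    adas <- 9.5 + truth$beta_gmv_cog[["adas_cog"]] * (med_true - base_med) +
      truth$beta_direct[["adas_cog"]] * score +
      rnorm(N, 0, truth$noise_sd_cog[["adas_cog"]])
    adas <- round(pmax(adas, 0), 1)
  })

  cbind(data.frame(subject_id = sprintf("S%04d", seq_len(N)),
                   group = group, age = age, gender = gender,
                   apoe4 = apoe4, education = education,
                   stringsAsFactors = FALSE),
        ind,
        data.frame(vrf_score = score, mediator_true = med_true,
                   mmse = mmse, adas_cog = adas))
}

# white noise on a padded grid, smoothed, cropped, standardized to unit
# per-voxel SD using the in-mask moments; shared by the generator and the
# cluster-null simulator so both live in the same smoothness world
smooth_noise_field <- function(grid_shape, voxel_size, fwhm_mm,
                               mask_data = NULL) {
  sigma_vox <- max(fwhm_mm * FWHM_TO_SIGMA / voxel_size)
  pad <- if (fwhm_mm > 0) as.integer(ceiling(4 * sigma_vox)) else 0L
  dpad <- grid_shape + 2L * pad
  noise <- array(rnorm(prod(dpad)), dim = dpad)
  if (fwhm_mm > 0) noise <- gaussian_smooth(noise, fwhm_mm, voxel_size)
  if (pad > 0)
    noise <- noise[(pad + 1):(pad + grid_shape[1]),
                   (pad + 1):(pad + grid_shape[2]),
                   (pad + 1):(pad + grid_shape[3]), drop = FALSE]
  ref <- if (is.null(mask_data)) noise else noise[mask_data]
  (noise - mean(ref)) / sd(ref)
}

#' Generate synthetic gray-matter volume images
#'
#' Per subject: `image = baseline template + group atrophy +
#' (beta_vrf_gmv * score + subject deviation)` inside the ROI masks
#' `+ noise_sd_image * (noise field smoothed to smoothing_fwhm_mm and
#' standardized to unit per-voxel SD)`, zero outside the brain mask. The
#' subject deviation is `mediator_true - expected mediator`, so the
#' noiseless ROI mean of the image reproduces the cohort's per-subject
#' true mediator exactly. The mean image value over the ROI
#' union is the *realized* mediator and is stored in the returned cohort
#' (`mediator_realized`), together with per-ROI means
#' (`roi_mean_<name>`). Deterministic given `truth$seed`.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param truth the matching [ground_truth()].
#' @return list with `images` (list of `volume`, one per subject), `mask`
#'   (brain-mask `volume`) and `cohort` (input cohort plus realized
#'   mediator columns).
#' @export
generate_gmv_images <- function(cohort, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  d <- truth$grid_shape
  tpl <- gm_template(truth)
  mask_data <- truth$brain_mask$data
  union_mask <- truth$roi_union
  N <- nrow(cohort)
  group_f <- factor(cohort$group, levels = GROUPS)
  group_i <- as.integer(group_f)
  # per-subject anatomical deviation recorded in the cohort's true mediator
  subj_dev <- if ("mediator_true" %in% names(cohort))
    cohort$mediator_true -
      expected_mediator(truth, group_f, cohort$vrf_score)
  else rep(0, N)

  images <- vector("list", N)
  roi_means <- matrix(NA_real_, N, length(truth$roi_masks),
                      dimnames = list(NULL, names(truth$roi_masks)))
  realized <- numeric(N)
  with_seed(truth$seed + 2L, {
    for (i in seq_len(N)) {
      img <- tpl
      img[mask_data] <- img[mask_data] +
        truth$group_atrophy[group_i[i]]
      img[union_mask] <- img[union_mask] +
        truth$beta_vrf_gmv * cohort$vrf_score[i] + subj_dev[i]
      if (truth$noise_sd_image > 0) {
        nf <- smooth_noise_field(d, truth$voxel_size,
                                 truth$smoothing_fwhm_mm, mask_data)
        img[mask_data] <- img[mask_data] +
          truth$noise_sd_image * nf[mask_data]
      }
      img[!mask_data] <- 0
      realized[i] <- mean(img[union_mask])
      for (r in seq_along(truth$roi_masks))
        roi_means[i, r] <- mean(img[as_volume_data(truth$roi_masks[[r]])])
      images[[i]] <- volume_image(img, truth$voxel_size,
                                  id = cohort$subject_id[i])
    }
  })
  cohort$mediator_realized <- realized
  for (r in colnames(roi_means))
    cohort[[paste0("roi_mean_", r)]] <- roi_means[, r]
  list(images = images, mask = truth$brain_mask, cohort = cohort)
}

#' Serialize ground truth as a JSON sidecar
#'
#' Masks are stored as run-length-free voxel index lists to keep the file
#' plain text and small.
#'
#' @param truth a [ground_truth()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- truth
  obj$brain_mask <- NULL
  obj$roi_union <- NULL
  obj$roi_masks <- lapply(truth$roi_masks,
                          function(m) which(as_volume_data(m)))
  obj$vrf_prevalence <- as.data.frame(truth$vrf_prevalence)
  # keep element names of named numeric vectors (JSON objects, not arrays)
  for (nm in names(obj))
    if (is.numeric(obj[[nm]]) && !is.null(names(obj[[nm]])))
      obj[[nm]] <- as.list(obj[[nm]])
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
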