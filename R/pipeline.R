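#' End-to-end pipeline orchestration
#'
#' One configuration drives the full analysis chain on synthetic data:
#' simulate cohort + images, score the VRFs, cohort statistics, voxel-wise
#' GLMs for the risk score and both cognitive outcomes, ANCOVA F-map,
#' Monte-Carlo cluster correction, conjunction of the corrected maps, ROI
#' extraction, and the mediation panel. Every stage result is kept in the
#' returned object, written under `out_dir` when given, and hashed into a
#' reproducibility manifest. Identical configurations (same seed) yield
#' identical outputs.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' A flat, JSON-serializable list of all pipeline settings with the
#' package defaults: voxel p = 0.01 two-tailed, cluster alpha = 0.05,
#' 6-connectivity, covariate-free mediation with 10,000 bootstrap samples.
#'
#' @param seed master seed.
#' @param out_dir output directory or `NULL` to keep results in memory.
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1, out_dir = NULL) {
  structure(list(
    seed = seed, out_dir = out_dir,
    truth = list(),                 # overrides for ground_truth()
    weights = NULL,                 # path to a weight table JSON, or NULL
    glm_covariates = c("age", "gender", "education", "apoe4"),
    glm_include_group = FALSE,
    ancova_covariates = c("age", "gender", "apoe4"),
    voxel_p = 0.01, alpha = 0.05, n_iter = 1000, connectivity = 6,
    two_tailed = TRUE, fwhm_from_residuals = TRUE,
    min_roi_size = 2,
    mediation_covariates = NULL,
    n_boot = 10000, ci_level = 0.95,
    stages = list(images = TRUE, glm = TRUE, cluster = TRUE,
                  conjunction = TRUE, mediation = TRUE),
    write_images = FALSE),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a list as produced by [default_config()] (possibly
#'   modified).
#' @return character vector of problems; empty iff the configuration is
#'   runnable.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  num_in <- function(x, lo, hi, closed_hi = TRUE)
    is.numeric(x) && length(x) >= 1 && all(x > lo) &&
      all(if (closed_hi) x <= hi else x < hi)
  if (is.null(config$seed) || !is.numeric(config$seed))
    add("seed: must be an integer")
  if (!is.null(config$alpha) && !num_in(config$alpha, 0, 1))
    add("alpha out of (0,1]")
  if (!is.null(config$voxel_p) && !num_in(config$voxel_p, 0, 1, FALSE))
    add("voxel_p out of (0,1)")
  if (!is.null(config$n_iter) && config$n_iter < 1)
    add("n_iter: must be >= 1")
  if (!is.null(config$n_boot) && config$n_boot < 1)
    add("n_boot: must be >= 1")
  if (!is.null(config$ci_level) && !num_in(config$ci_level, 0, 1, FALSE))
    add("ci_level out of (0,1)")
  if (!is.null(config$connectivity) &&
      !config$connectivity %in% c(6, 18, 26))
    add("connectivity: must be 6, 18 or 26")
  if (!is.null(config$weights)) {
    if (!file.exists(config$weights))
      add(paste0("weights: file not found: ", config$weights))
  }
  for (f in c("glm_covariates", "ancova_covariates"))
    if (!is.null(config[[f]]) && !is.character(config[[f]]))
      add(paste0(f, ": must be a character vector"))
  problems
}

manifest_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f)   # scratch only; never shipped
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' @param config a validated configuration list; see [default_config()].
#' @return list of class `pipeline_run` with elements `truth`, `cohort`,
#'   `cohort_stats`, `glm` (per predictor), `ancova`, `smoothness`,
#'   `cluster_table`, `corrected` (per predictor), `conjunctions`, `rois`,
#'   `roi_means`, `mediation` (per outcome), and `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  run <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  t0 <- Sys.time()

  ## -- simulate + score ----------------------------------------------------
  run$truth <- stage("simulate",
    do.call(ground_truth, c(config$truth, list(seed = config$seed))))
  cohort <- stage("simulate", generate_cohort(run$truth))
  weights <- if (is.null(config$weights))
    setNames(rep(1, 6), VRF_FACTORS) else read_vrf_weights(config$weights)
  cohort <- stage("score", score_cohort(cohort, weights = weights))

  ## -- cohort statistics ---------------------------------------------------
  run$cohort_stats <- stage("cohort_stats", list(
    table1 = cohort_table1(cohort),
    vrf_anova = anova_oneway(cohort$vrf_score, cohort$group),
    posthoc = posthoc_pairwise(cohort$vrf_score, cohort$group,
                               reference = "AD")))

  if (isTRUE(config$stages$images)) {
    gen <- stage("simulate", generate_gmv_images(cohort, run$truth))
    cohort <- gen$cohort
    images <- gen$images
    mask <- gen$mask
    run$mask <- mask
    # Fig.-1-style partial correlation needs total gray matter volume
    tgm <- vapply(images, function(im)
      sum(im$data[mask$data]) * voxel_volume_mm3(im), numeric(1))
    cohort$total_gmv <- tgm
    run$cohort_stats$partial_mmse <- stage("cohort_stats",
      partial_correlation(cohort$vrf_score, cohort$mmse,
                          cohort[c("age", "gender", "apoe4", "total_gmv")]))
    run$cohort_stats$partial_adas <- stage("cohort_stats",
      partial_correlation(cohort$vrf_score, cohort$adas_cog,
                          cohort[c("age", "gender", "apoe4", "total_gmv")]))
  }
  run$cohort <- cohort

  ## -- voxel-wise models ---------------------------------------------------
  if (isTRUE(config$stages$images) && isTRUE(config$stages$glm)) {
    predictors <- c(vrf = "vrf_score", mmse = "mmse", adas_cog = "adas_cog")
    run$glm <- lapply(predictors, function(pv)
      stage(paste0("glm:", pv), fit_glm(
        images, mask,
        build_design(cohort, pv, config$glm_covariates,
                     include_group = config$glm_include_group))))
    run$ancova <- stage("ancova", fit_ancova(
      images, mask, cohort$group,
      cohort[config$ancova_covariates]))
    run$smoothness <- stage("smoothness",
                            estimate_smoothness(run$glm$vrf))
  }

  ## -- cluster correction --------------------------------------------------
  if (isTRUE(config$stages$images) && isTRUE(config$stages$glm) &&
      isTRUE(config$stages$cluster)) {
    fwhm <- if (isTRUE(config$fwhm_from_residuals))
      run$smoothness$mean_fwhm_mm else run$truth$smoothing_fwhm_mm
    run$cluster_table <- stage("cluster", simulate_cluster_null(
      mask, fwhm, voxel_p = config$voxel_p, alpha = config$alpha,
      n_iter = config$n_iter, seed = config$seed + 3,
      connectivity = config$connectivity,
      two_tailed = config$two_tailed))
    run$corrected <- lapply(run$glm, function(g)
      stage("cluster", apply_cluster_correction(
        g$z, run$cluster_table, config$voxel_p, config$alpha)))
  }

  ## -- conjunction + ROI extraction ----------------------------------------
  if (!is.null(run$corrected) && isTRUE(config$stages$conjunction)) {
    run$conjunctions <- list(
      mmse = conjunction(run$corrected$vrf$mask, run$corrected$mmse$mask),
      adas_cog = conjunction(run$corrected$vrf$mask,
                             run$corrected$adas_cog$mask))
    run$rois <- lapply(run$conjunctions, split_rois,
                       connectivity = config$connectivity,
                       min_size = config$min_roi_size)
    run$roi_means <- lapply(run$rois, function(rs)
      if (length(rs$masks)) extract_roi_means(images, rs) else NULL)
  }

  ## -- mediation -----------------------------------------------------------
  if (!is.null(run$rois) && isTRUE(config$stages$mediation)) {
    run$mediation <- list()
    for (oc in c("mmse", "adas_cog")) {
      rm_ <- run$roi_means[[oc]]
      if (is.null(rm_)) next
      run$mediation[[oc]] <- stage(paste0("mediation:", oc),
        run_mediation_panel(cohort, rm_, outcomes = oc,
                            covariates = config$mediation_covariates,
                            n_boot = config$n_boot,
                            seed = config$seed + 5,
                            ci_level = config$ci_level))
    }
  }

  ## -- outputs + manifest --------------------------------------------------
  manifest <- list(
    package = "vrfmed",
    version = as.character(packageVersion("vrfmed")),
    seed = config$seed,
    settings = config[c("voxel_p", "alpha", "n_iter", "connectivity",
                        "two_tailed", "n_boot", "ci_level")],
    started = format(t0), elapsed_s = NULL,
    hashes = list(
      cohort = manifest_hash(run$cohort),
      cluster_table = if (!is.null(run$cluster_table))
        manifest_hash(run$cluster_table$table),
      mediation = if (!is.null(run$mediation))
        manifest_hash(run$mediation)))

  if (!is.null(out_dir)) {
    write.csv(run$cohort, file.path(out_dir, "cohort_scored.csv"),
              row.names = FALSE)
    if (!is.null(run$mask))
      write_nifti(run$mask, file.path(out_dir, "brain_mask.nii.gz"),
                  datatype = "uint8")
    if (isTRUE(config$write_images) && isTRUE(config$stages$images))
      for (im in images)
        write_nifti(im, file.path(out_dir,
                                  paste0("gmv_", im$id, ".nii.gz")))
    if (!is.null(run$glm))
      for (nm in names(run$glm))
        write_nifti(run$glm[[nm]]$z,
                    file.path(out_dir, paste0("zmap_", nm, ".nii.gz")))
    if (!is.null(run$cluster_table))
      write_cluster_table(run$cluster_table,
                          file.path(out_dir, "cluster_table.json"))
    if (!is.null(run$rois))
      for (nm in names(run$rois))
        if (length(run$rois[[nm]]$masks)) {
          write_nifti(volume_image(run$rois[[nm]]$labels,
                                   run$rois[[nm]]$voxel_size),
                      file.path(out_dir, paste0("rois_", nm, ".nii.gz")),
                      datatype = "int16")
          write.csv(run$roi_means[[nm]],
                    file.path(out_dir, paste0("roi_means_", nm, ".csv")),
                    row.names = FALSE)
        }
    if (!is.null(run$mediation))
      for (nm in names(run$mediation))
        write.table(run$mediation[[nm]],
                    file.path(out_dir, paste0("mediation_", nm, ".tsv")),
                    sep = "\t", row.names = FALSE, quote = FALSE)
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  run$manifest <- manifest
  if (!is.null(out_dir)) {
    m <- manifest; m$elapsed_s <- NULL; m$started <- NULL  # hash-stable
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(run) <- "pipeline_run"
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: n = %d subjects, seed %d>\n",
              nrow(x$cohort), x$config$seed))
  if (!is.null(x$smoothness)) print(x$smoothness)
  if (!is.null(x$rois))
    for (nm in names(x$rois))
      cat(sprintf("  conjunction[%s]: %d ROIs\n", nm,
                  length(x$rois[[nm]]$masks)))
  if (!is.null(x$mediation))
    for (nm in names(x$mediation)) {
      md <- x$mediation[[nm]]
      cat(sprintf("  mediation[%s]: %d results, %d significant\n",
                  nm, nrow(md), sum(md$significant)))
    }
  invisible(x)
}
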