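#' Vascular risk factor binarization and composite scoring
#'
#' Six modifiable vascular risk factors (VRFs) are coded present/absent per
#' subject and combined into a composite score. The clinical criteria are:
#'
#' * **diabetes** — self-reported diabetes, OR use of antidiabetic therapy,
#'   OR casual blood glucose >= 200 mg/dl;
#' * **hypertension** — untreated systolic blood pressure >= 140 mmHg, OR
#'   untreated diastolic blood pressure >= 90 mmHg, OR use of
#'   antihypertensive medication (medicated subjects count as hypertensive
#'   regardless of their readings);
#' * **smoking** — self-report of at least 20 cigarettes/day;
#' * **depression** — lifetime diagnosis of major depressive disorder;
#' * **low_education** — low educational attainment flag (ISCED level <= 2);
#' * **obesity** — body-mass index strictly greater than 30 kg/m^2.
#'
#' Boundary semantics are fixed: `>=` for glucose, blood pressure and
#' cigarettes; strict `>` for BMI. Missing measurements are represented as
#' `NA` and are distinct from "absent": a factor whose every contributing
#' measurement is missing yields an `NA` indicator rather than a silent 0.
#'
#' @name vrf-scoring
NULL

VRF_FACTORS <- c("diabetes", "hypertension", "smoking", "depression",
                 "low_education", "obesity")

or3 <- function(...) {
  args <- list(...)
  known_true <- Reduce(`|`, lapply(args, function(a) !is.na(a) & a))
  all_na <- Reduce(`&`, lapply(args, is.na))
  out <- ifelse(known_true, 1L, ifelse(all_na, NA_integer_, 0L))
  out
}

#' Binarize the six vascular risk factors
#'
#' Vectorized over subjects: every argument may be a scalar or a vector of
#' equal length. Booleans may be given as logical or 0/1; `NA` means
#' missing.
#'
#' @param diabetes_selfreport,antidiabetic_meds logical.
#' @param glucose_mg_dl casual blood glucose, mg/dl (validated to
#'   \[20, 1000\] when present).
#' @param sbp_mmHg,dbp_mmHg blood pressures (SBP validated to \[60, 300\],
#'   DBP to \[30, 200\]).
#' @param antihypertensive_meds logical.
#' @param cigarettes_per_day numeric >= 0.
#' @param major_depression_dx,low_education_flag logical.
#' @param bmi_kg_m2 numeric > 0.
#' @return data.frame of six 0/1 (or `NA`) indicator columns named
#'   `r paste(VRF_FACTORS, collapse = ", ")`.
#' @export
#' @examples
#' vrf_indicators(sbp_mmHg = 150, dbp_mmHg = 80,
#'                antihypertensive_meds = FALSE)$hypertension  # 1
vrf_indicators <- function(diabetes_selfreport = NA,
                           antidiabetic_meds = NA,
                           glucose_mg_dl = NA_real_,
                           sbp_mmHg = NA_real_,
                           dbp_mmHg = NA_real_,
                           antihypertensive_meds = NA,
                           cigarettes_per_day = NA_real_,
                           major_depression_dx = NA,
                           low_education_flag = NA,
                           bmi_kg_m2 = NA_real_) {
  check_range <- function(x, lo, hi, nm) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad))
      stop(sprintf("%s outside physiologic range [%g, %g]: %s",
                   nm, lo, hi, paste(x[bad], collapse = ", ")))
    x
  }
  glucose_mg_dl <- check_range(glucose_mg_dl, 20, 1000, "glucose_mg_dl")
  sbp_mmHg <- check_range(sbp_mmHg, 60, 300, "sbp_mmHg")
  dbp_mmHg <- check_range(dbp_mmHg, 30, 200, "dbp_mmHg")
  cigarettes_per_day <- check_range(cigarettes_per_day, 0, 200,
                                    "cigarettes_per_day")
  bmi_kg_m2 <- check_range(bmi_kg_m2, 5, 120, "bmi_kg_m2")

  n <- max(lengths(list(diabetes_selfreport, antidiabetic_meds,
                        glucose_mg_dl, sbp_mmHg, dbp_mmHg,
                        antihypertensive_meds, cigarettes_per_day,
                        major_depression_dx, low_education_flag,
                        bmi_kg_m2)))
  rl <- function(x) rep_len(x, n)

  meds <- rl(antihypertensive_meds)
  untreated <- !is.na(meds) & !meds
  # untreated BP thresholds only apply off-medication; on medication the
  # subject is hypertensive by definition
  sbp_high <- ifelse(is.na(rl(sbp_mmHg)), NA, rl(sbp_mmHg) >= 140) & untreated
  dbp_high <- ifelse(is.na(rl(dbp_mmHg)), NA, rl(dbp_mmHg) >= 90) & untreated

  data.frame(
    diabetes = or3(rl(diabetes_selfreport), rl(antidiabetic_meds),
                   ifelse(is.na(rl(glucose_mg_dl)), NA,
                          rl(glucose_mg_dl) >= 200)),
    hypertension = or3(sbp_high, dbp_high, meds),
    smoking = or3(ifelse(is.na(rl(cigarettes_per_day)), NA,
                         rl(cigarettes_per_day) >= 20)),
    depression = or3(rl(major_depression_dx)),
    low_education = or3(rl(low_education_flag)),
    obesity = or3(ifelse(is.na(rl(bmi_kg_m2)), NA, rl(bmi_kg_m2) > 30))
  )
}

#' Composite VRF score
#'
#' The composite score is the weighted sum of the six 0/1 indicators,
#' `sum_f weight_f * indicator_f`. With unit weights (the default) it is the
#' count of present factors, an integer in 0..6. Weights are per-factor
#' relative-risk values supplied as a named vector or a weight-table file
#' (see [read_vrf_weights()]).
#'
#' @param indicators data.frame or named list with the six indicator columns
#'   (as produced by [vrf_indicators()]), values in \{0, 1, NA\}.
#' @param weights named numeric vector of positive per-factor weights; names
#'   must cover all six factors. Default: unit weights.
#' @param missing one of `"strict"` (default; any `NA` indicator is an
#'   error) or `"zero"` (`NA` treated as absent, with a warning).
#' @return numeric vector of composite scores, one per subject.
#' @export
#' @examples
#' ind <- vrf_indicators(glucose_mg_dl = 210, cigarettes_per_day = 20,
#'                       diabetes_selfreport = FALSE,
#'                       antidiabetic_meds = FALSE, sbp_mmHg = 120,
#'                       dbp_mmHg = 80, antihypertensive_meds = FALSE,
#'                       major_depression_dx = FALSE,
#'                       low_education_flag = FALSE, bmi_kg_m2 = 24)
#' vrf_composite(ind, weights = c(diabetes = 1.46, hypertension = 1.61,
#'                                smoking = 1.59, depression = 1.65,
#'                                low_education = 1.59, obesity = 1.6))
vrf_composite <- function(indicators,
                          weights = setNames(rep(1, 6), VRF_FACTORS),
                          missing = c("strict", "zero")) {
  missing <- match.arg(missing)
  if (!all(VRF_FACTORS %in% names(indicators)))
    stop("indicators must contain columns: ",
         paste(setdiff(VRF_FACTORS, names(indicators)), collapse = ", "))
  if (!all(VRF_FACTORS %in% names(weights)))
    stop("weights must be named for all six factors")
  w <- as.numeric(weights[VRF_FACTORS])
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")

  M <- as.matrix(as.data.frame(indicators)[VRF_FACTORS])
  storage.mode(M) <- "numeric"
  if (!all(M %in% c(0, 1) | is.na(M)))
    stop("indicators must be 0/1 or NA")
  if (anyNA(M)) {
    if (missing == "strict")
      stop("missing VRF indicators under 'strict' policy; ",
           "use missing = \"zero\" to impute absent")
    warning(sum(is.na(M)), " missing VRF indicators treated as absent")
    M[is.na(M)] <- 0
  }
  as.numeric(M %*% w)
}

#' Read / write a VRF weight table
#'
#' Weight tables are JSON objects mapping factor name to a positive
#' relative-risk weight, with an optional `"id"` field naming the table
#' version. An editable example is shipped at
#' `system.file("extdata", "vrf_weights_example.json", package = "vrfmed")`.
#'
#' @param path JSON file path.
#' @return named numeric weight vector with attribute `"id"`.
#' @export
read_vrf_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  id <- if (!is.null(obj$id)) obj$id else tools::file_path_sans_ext(basename(path))
  w <- unlist(obj[VRF_FACTORS])
  if (length(w) != 6L || anyNA(w))
    stop("weight table must define all six factors: ",
         paste(VRF_FACTORS, collapse = ", "))
  w <- setNames(as.numeric(w), VRF_FACTORS)
  attr(w, "id") <- id
  w
}

#' Score a cohort table
#'
#' Adds the six indicator columns (if raw measures are present) and the
#' `vrf_score` column to a cohort data.frame. If the table already contains
#' the indicator columns they are used as-is.
#'
#' @param cohort data.frame; either six indicator columns named as in
#'   [vrf_indicators()], or the raw measure columns accepted by it.
#' @param weights,missing passed to [vrf_composite()].
#' @return the cohort with a `vrf_score` column appended/replaced.
#' @export
score_cohort <- function(cohort,
                         weights = setNames(rep(1, 6), VRF_FACTORS),
                         missing = "strict") {
  if (!all(VRF_FACTORS %in% names(cohort))) {
    raw_args <- intersect(names(formals(vrf_indicators)), names(cohort))
    if (length(raw_args) == 0L)
      stop("cohort has neither VRF indicator columns nor raw measures")
    ind <- do.call(vrf_indicators, cohort[raw_args])
    cohort[VRF_FACTORS] <- ind
  }
  cohort$vrf_score <- vrf_composite(cohort[VRF_FACTORS], weights = weights,
                                    missing = missing)
  cohort
}
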