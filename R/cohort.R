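#' Names of the fifteen dichotomous risk predictors
#'
#' Returns the canonical predictor names used throughout the package, in the
#' fixed order in which they appear in cohort tables and association panels.
#'
#' @return Character vector of length 15.
#' @export
predictor_names <- function() {
  c("pituitary_dysgenesis",
    "midline_abnormality",
    "sellar_tumor_surgery",
    "cns_infection",
    "severe_tbi",
    "cranial_radiotherapy_ge18Gy",
    "chemotherapy_ge6mo",
    "genetic_ghd",
    "tsh_deficiency",
    "acth_deficiency",
    "prolactin_deficiency",
    "central_diabetes_insipidus",
    "neonatal_hypoglycemia",
    "neonatal_cholestasis",
    "neonatal_hypogenitalism")
}

#' Era-dependent GH peak cut-off table
#'
#' GHD ascertainment uses a strict peak-GH cut-off that changed with the GH
#' assay standard: 6.1 ng/ml for tests performed 2004--2011 and 4.7 ng/ml
#' from 2012 onwards. The table is configurable so other centres' windows
#' can be substituted.
#'
#' @param from,to Integer calendar years delimiting each window (inclusive).
#' @param cutoff Peak GH cut-off in ng/ml for each window.
#' @return A `data.frame` with columns `from`, `to`, `cutoff`.
#' @export
era_cutoffs <- function(from = c(2004L, 2012L),
                        to = c(2011L, 2019L),
                        cutoff = c(6.1, 4.7)) {
  stopifnot(length(from) == length(to), length(to) == length(cutoff),
            all(from <= to), all(cutoff > 0))
  data.frame(from = as.integer(from), to = as.integer(to), cutoff = cutoff)
}

#' Look up the GH cut-off applying to a test year
#'
#' @param era Calendar year of the stimulation test.
#' @param cutoffs Cut-off table from [era_cutoffs()].
#' @return The cut-off in ng/ml.
#' @export
gh_cutoff <- function(era, cutoffs = era_cutoffs()) {
  stopifnot(length(era) == 1L, is.finite(era))
  hit <- which(cutoffs$from <= era & era <= cutoffs$to)
  if (length(hit) != 1L) {
    stop("era ", era, " maps to ", length(hit),
         " cut-off windows; exactly one is required", call. = FALSE)
  }
  cutoffs$cutoff[hit]
}

#' Ascertain GHD status from stimulation-test peaks
#'
#' A patient is a GHD case when the maximal stimulated GH concentration
#' across all test arms is strictly below the era cut-off; a control when at
#' least one peak reaches the cut-off.
#'
#' @param gh_peaks Numeric vector of per-arm peak GH values (ng/ml),
#'   non-empty.
#' @param era Calendar year of testing.
#' @param cutoffs Cut-off table, see [era_cutoffs()].
#' @return `"case"` or `"control"`.
#' @examples
#' ascertain_ghd(c(3.2, 5.0), era = 2008)  # "case": max 5.0 < 6.1
#' ascertain_ghd(6.71, era = 2018)         # "control"
#' @export
ascertain_ghd <- function(gh_peaks, era, cutoffs = era_cutoffs()) {
  if (length(gh_peaks) == 0L || all(is.na(gh_peaks))) {
    stop("gh_peaks must contain at least one recorded GH peak", call. = FALSE)
  }
  if (any(gh_peaks < 0, na.rm = TRUE)) {
    stop("gh_peaks contains negative concentrations", call. = FALSE)
  }
  cut <- gh_cutoff(era, cutoffs)
  if (max(gh_peaks, na.rm = TRUE) < cut) "case" else "control"
}

#' Screen a patient against the GHST eligibility criteria
#'
#' Implements the Growth Hormone Research Society auxologic criteria that
#' justify a stimulation test. A patient is eligible when any criterion
#' holds; all satisfied criteria are returned. Missing optional fields
#' simply cannot satisfy their criterion. The two sign-based criteria
#' (intracranial lesion, multiple pituitary deficiency) and neonatal signs
#' are accepted as booleans since no operational definition exists for them.
#'
#' @param record A list or one-row data.frame with at least `height_sds`;
#'   optionally `midparental_height_sds`, `height_velocity_sds`,
#'   `height_velocity_sds_2yr`, `delta_height_sds_1yr`, `age_years`,
#'   `intracranial_lesion_signs`, `mpd_signs`, `neonatal_ghd_signs`.
#' @return List with `eligible` (logical) and `criteria` (character vector
#'   of satisfied criteria, possibly empty).
#' @export
check_eligibility <- function(record) {
  g <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) == 0L) NA else v[[1L]]
  }
  num <- function(f) { v <- g(f); if (is.na(v)) NA_real_ else as.numeric(v) }
  flag <- function(f) isTRUE(as.logical(g(f)))

  h   <- num("height_sds")
  if (is.na(h)) stop("height_sds is required for eligibility screening",
                     call. = FALSE)
  mph <- num("midparental_height_sds")
  hv  <- num("height_velocity_sds")
  hv2 <- num("height_velocity_sds_2yr")
  dh  <- num("delta_height_sds_1yr")
  age <- num("age_years")

  crit <- character(0)
  if (h < -3) crit <- c(crit, "severe_short_stature")
  if (!is.na(mph) && h < mph - 1.5) crit <- c(crit, "below_midparental_height")
  if (h < -2 && ((!is.na(hv) && hv < -1) ||
                 (!is.na(dh) && !is.na(age) && dh < -0.5 && age > 2))) {
    crit <- c(crit, "short_stature_with_growth_deceleration")
  }
  if ((!is.na(hv) && hv < -2) || (!is.na(hv2) && hv2 < -1.5)) {
    crit <- c(crit, "low_height_velocity")
  }
  if (flag("intracranial_lesion_signs")) crit <- c(crit, "intracranial_lesion_signs")
  if (flag("mpd_signs")) crit <- c(crit, "multiple_pituitary_deficiency_signs")
  if (flag("neonatal_ghd_signs")) crit <- c(crit, "neonatal_ghd_signs")

  list(eligible = length(crit) > 0L, criteria = crit)
}

#' Ascertain GHD status for every patient in a cohort
#'
#' Parses the per-patient GH peak list and applies [ascertain_ghd()] with
#' the era cut-off table. Patients weighing 10 kg or more must have at least
#' two recorded test arms (sequential arginine-clonidine testing); lighter
#' patients may have one.
#'
#' @param cohort A cohort data.frame (see [read_cohort()] for the schema).
#' @param cutoffs Cut-off table from [era_cutoffs()].
#' @return The cohort with `ghd_status` filled in.
#' @export
ascertain_cohort <- function(cohort, cutoffs = era_cutoffs()) {
  peaks <- parse_gh_peaks(cohort$gh_peaks)
  n_arm <- lengths(peaks)
  heavy <- !is.na(cohort$weight_kg) & cohort$weight_kg >= 10
  bad <- which(heavy & n_arm < 2L)
  if (length(bad) > 0L) {
    stop("patients weighing >= 10 kg require two sequential GHSTs; ",
         "offending rows: ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  cohort$ghd_status <- vapply(seq_len(nrow(cohort)), function(i) {
    ascertain_ghd(peaks[[i]], cohort$era[i], cutoffs)
  }, character(1))
  cohort
}

#' @keywords internal
parse_gh_peaks <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- suppressWarnings(as.numeric(v))
    v[!is.na(v)]
  })
}
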