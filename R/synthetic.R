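#' @name synthetic_cohort
#' @title Seeded synthetic patient cohorts
#' @description The generator emulates the statistical structure the
#'   analysis assumes -- case prevalence, per-predictor conditional rates,
#'   correlated comorbidity profiles (congenital multiple-deficiency,
#'   acquired tumor/radiation, neonatal-onset and idiopathic archetypes),
#'   auxology distributions and differential MRI availability -- so the
#'   whole pipeline can run without patient data. In `exact_marginal` mode
#'   the predictor flags are instantiated from a fixed joint template whose
#'   per-predictor 2x2 tables equal the calibration targets exactly and
#'   whose control profiles never satisfy the prediction rule; the seed
#'   then only drives demographics, auxology and GH peaks. In `stochastic`
#'   mode patient profiles are resampled from that template (preserving the
#'   joint dependence between flags) with Bernoulli case status, so
#'   conditional rates converge to the targets as n grows.
NULL

flag_template <- function(n) {
  df <- as.data.frame(stats::setNames(
    rep(list(rep(FALSE, n)), length(predictor_names())),
    predictor_names()))
  df$mri_available <- rep(FALSE, n)
  df
}

set_rows <- function(df, rows, col, value = TRUE) {
  df[rows, col] <- value
  df
}

# Joint flag template for the 770-patient derivation cohort: 150 cases and
# 620 controls. Case rows are organised into clinical archetypes:
#   rows  1-20  congenital MPHD with pituitary dysgenesis (multiple
#               anterior deficiencies, diabetes insipidus, neonatal signs)
#   rows 21-38  congenital isolated GHD with dysgenesis
#   rows 39-51  acquired/multiple-deficiency cases without dysgenesis
#               (tumor, radiotherapy, chemotherapy; two anterior
#               deficiencies)
#   rows 52-61  single anterior deficiency plus one comorbidity
#   rows 62-150 rule-negative cases (idiopathic or isolated findings)
# Every per-predictor case/control margin matches the calibration counts,
# and no control profile satisfies the prediction rule.
derivation_case_template <- function() {
  df <- flag_template(150)
  df <- set_rows(df, 1:38, "pituitary_dysgenesis")
  # anterior deficiencies and diabetes insipidus in the dysgenesis group
  df <- set_rows(df, 1:18, "tsh_deficiency")
  df <- set_rows(df, 1:16, "acth_deficiency")
  df <- set_rows(df, 1:3, "prolactin_deficiency")
  df <- set_rows(df, 15:20, "central_diabetes_insipidus")
  # comorbidities spread over the dysgenesis group
  df <- set_rows(df, c(1:5, 21:25), "midline_abnormality")
  df <- set_rows(df, c(1:6, 26:29), "neonatal_hypoglycemia")
  df <- set_rows(df, c(7:12, 30:35), "neonatal_hypogenitalism")
  df <- set_rows(df, 13:15, "neonatal_cholestasis")
  df <- set_rows(df, 36:37, "genetic_ghd")
  # acquired / two-deficiency archetype (rows 39-51)
  df <- set_rows(df, 39:51, "tsh_deficiency")
  df <- set_rows(df, 39:51, "acth_deficiency")
  df <- set_rows(df, 39:44, "sellar_tumor_surgery")
  df <- set_rows(df, 39:42, "cranial_radiotherapy_ge18Gy")
  df <- set_rows(df, 41:44, "chemotherapy_ge6mo")
  df <- set_rows(df, 45:46, "neonatal_hypoglycemia")
  df <- set_rows(df, 47:48, "neonatal_hypogenitalism")
  # one deficiency plus one qualifying comorbidity (rows 52-61)
  df <- set_rows(df, 52:59, "tsh_deficiency")
  df <- set_rows(df, 52:59, "central_diabetes_insipidus")
  df <- set_rows(df, 60:61, "acth_deficiency")
  df <- set_rows(df, 60, "midline_abnormality")
  df <- set_rows(df, 61, "sellar_tumor_surgery")
  # rule-negative cases (rows 62-150)
  df <- set_rows(df, 62:64, "tsh_deficiency")          # 1 deficiency only
  df <- set_rows(df, 65, "acth_deficiency")
  df <- set_rows(df, 66:68, "central_diabetes_insipidus")  # DI only
  df <- set_rows(df, 69:76, "midline_abnormality")
  df <- set_rows(df, 77:82, "sellar_tumor_surgery")
  df <- set_rows(df, 83:88, "neonatal_hypoglycemia")
  df <- set_rows(df, 89:92, "neonatal_hypogenitalism")
  df <- set_rows(df, 93:98, "cranial_radiotherapy_ge18Gy")
  df <- set_rows(df, 96:101, "chemotherapy_ge6mo")
  df <- set_rows(df, 102, "genetic_ghd")
  df <- set_rows(df, 103, "severe_tbi")
  df <- set_rows(df, 104:105, "neonatal_cholestasis")
  # MRI performed in 120 of 150 cases; dysgenesis unknown in the rest
  df$mri_available <- c(rep(TRUE, 120), rep(FALSE, 30))
  df$pituitary_dysgenesis[!df$mri_available] <- NA
  df
}

derivation_control_template <- function() {
  df <- flag_template(620)
  # the single TSH-deficient control carries no qualifying comorbidity
  df <- set_rows(df, 1, "tsh_deficiency")
  df <- set_rows(df, 2:18, "midline_abnormality")
  df <- set_rows(df, 19:21, "sellar_tumor_surgery")
  df <- set_rows(df, 22:27, "cns_infection")
  df <- set_rows(df, 28:29, "severe_tbi")
  df <- set_rows(df, 30:39, "cranial_radiotherapy_ge18Gy")
  df <- set_rows(df, 37:47, "chemotherapy_ge6mo")
  df <- set_rows(df, 48, "genetic_ghd")
  df <- set_rows(df, 49:52, "central_diabetes_insipidus")
  df <- set_rows(df, 53:64, "neonatal_hypoglycemia")
  df <- set_rows(df, 65:68, "neonatal_cholestasis")
  df <- set_rows(df, 69:76, "neonatal_hypogenitalism")
  df$mri_available <- c(rep(TRUE, 98), rep(FALSE, 522))
  df$pituitary_dysgenesis[!df$mri_available] <- NA
  df
}

# Validation-cohort template: 36 cases (20 rule-positive) and 125 controls
# with exactly one rule-positive control, reproducing the validation
# confusion matrix TP=20 / FP=1 / FN=16 / TN=124.
validation_case_template <- function() {
  df <- flag_template(36)
  df <- set_rows(df, 1:5, "pituitary_dysgenesis")        # isolated GHD
  df <- set_rows(df, 6:15, "tsh_deficiency")             # two deficiencies
  df <- set_rows(df, 6:15, "acth_deficiency")
  df <- set_rows(df, 16:20, "tsh_deficiency")            # one + DI
  df <- set_rows(df, 16:20, "central_diabetes_insipidus")
  df <- set_rows(df, 21, "acth_deficiency")              # negative MPHD
  df$mri_available <- c(rep(TRUE, 27), rep(FALSE, 9))
  df$pituitary_dysgenesis[!df$mri_available] <- NA
  df
}

validation_control_template <- function() {
  df <- flag_template(125)
  # the single false positive: one deficiency plus neonatal hypoglycemia
  df <- set_rows(df, 1, "tsh_deficiency")
  df <- set_rows(df, 1, "neonatal_hypoglycemia")
  df <- set_rows(df, 2:4, "midline_abnormality")
  df <- set_rows(df, 5:6, "central_diabetes_insipidus")
  df <- set_rows(df, 7:9, "neonatal_hypoglycemia")
  df <- set_rows(df, 10:11, "neonatal_hypogenitalism")
  df <- set_rows(df, 12, "cranial_radiotherapy_ge18Gy")
  df <- set_rows(df, 13:14, "chemotherapy_ge6mo")
  df$mri_available <- c(rep(TRUE, 19), rep(FALSE, 106))
  df$pituitary_dysgenesis[!df$mri_available] <- NA
  df
}

#' Construct a cohort-simulation specification
#'
#' @param name Spec name (used in patient ids).
#' @param n Cohort size.
#' @param n_case Number of GHD cases (exact mode) / expected (stochastic).
#' @param era_from,era_to Calendar-year window of testing.
#' @param male_frac Proportion of boys.
#' @param age Named vector `c(median=, sd=)` for age in years.
#' @param height_sds,weight_sds,bmi_sds Named vectors `c(median=, sd=)` for
#'   the auxology SDS distributions (normal location-scale; the SD is the
#'   IQR divided by 1.349).
#' @param igf1_case,igf1_control Named vectors `c(median=, sd=)` for IGF1
#'   SDS by status.
#' @param pubertal_probs Probabilities of Tanner stages 1-5.
#' @param case_template,control_template Joint flag templates (data.frames
#'   with the 15 predictor columns plus `mri_available`).
#' @param mode Default simulation mode, `"exact_marginal"` or
#'   `"stochastic"`.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n, n_case, era_from, era_to, male_frac,
                        age, height_sds, weight_sds, bmi_sds,
                        igf1_case, igf1_control, pubertal_probs,
                        case_template, control_template,
                        mode = "exact_marginal") {
  stopifnot(n >= 0, n_case >= 0, n_case <= n,
            era_from <= era_to, male_frac >= 0, male_frac <= 1,
            abs(sum(pubertal_probs) - 1) < 1e-6,
            nrow(case_template) == n_case,
            nrow(control_template) == n - n_case,
            all(c(predictor_names(), "mri_available") %in%
                  names(case_template)))
  structure(list(name = name, n = n, n_case = n_case,
                 prevalence = if (n > 0) n_case / n else NA_real_,
                 era_from = era_from, era_to = era_to,
                 male_frac = male_frac, age = age,
                 height_sds = height_sds, weight_sds = weight_sds,
                 bmi_sds = bmi_sds, igf1_case = igf1_case,
                 igf1_control = igf1_control,
                 pubertal_probs = pubertal_probs,
                 case_template = case_template,
                 control_template = control_template, mode = mode),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: n=%d, cases=%d (prevalence %.3f), era %d-%d\n",
              x$name, x$n, x$n_case, x$prevalence, x$era_from, x$era_to))
  invisible(x)
}

#' Built-in cohort specifications
#'
#' Returns the two calibrated specifications: the 2004--2014 derivation
#' cohort (n = 770, 150 GHD, peak-GH cut-offs 6.1/4.7 ng/ml by era, MRI in
#' 218 patients) and the 2017--2019 validation cohort (n = 161, 36 GHD).
#' Auxology locations and scales are taken from the published medians and
#' interquartile ranges; flag templates encode the per-predictor
#' case/control margins and the rule-consistency constraints.
#'
#' @return Named list with `derivation_2004_2014` and
#'   `validation_2017_2019`.
#' @export
default_specs <- function() {
  iqr_sd <- function(q1, q3) (q3 - q1) / (2 * stats::qnorm(0.75))
  list(
    derivation_2004_2014 = cohort_spec(
      name = "derivation_2004_2014", n = 770, n_case = 150,
      era_from = 2004, era_to = 2014, male_frac = 491 / 770,
      age = c(median = 7.74, sd = iqr_sd(5.22, 11.08)),
      height_sds = c(median = -2.51, sd = iqr_sd(-3.02, -2.20)),
      weight_sds = c(median = -2.30, sd = iqr_sd(-2.77, -1.71)),
      bmi_sds = c(median = -0.50, sd = iqr_sd(-0.94, -0.24)),
      igf1_case = c(median = -2.92, sd = iqr_sd(-4.68, -1.77)),
      igf1_control = c(median = -1.54, sd = iqr_sd(-3.11, -0.37)),
      pubertal_probs = c(609, 99, 51, 10, 1) / 770,
      case_template = derivation_case_template(),
      control_template = derivation_control_template()),
    validation_2017_2019 = cohort_spec(
      name = "validation_2017_2019", n = 161, n_case = 36,
      era_from = 2017, era_to = 2019, male_frac = 111 / 161,
      age = c(median = 7.67, sd = iqr_sd(5.1, 11.2)),
      height_sds = c(median = -2.57, sd = iqr_sd(-3.07, -2.02)),
      weight_sds = c(median = -2.20, sd = iqr_sd(-2.80, -1.40)),
      bmi_sds = c(median = -0.30, sd = iqr_sd(-0.88, -0.10)),
      igf1_case = c(median = -1.78, sd = iqr_sd(-2.80, -0.50)),
      igf1_control = c(median = -0.09, sd = iqr_sd(-1.02, 0.48)),
      pubertal_probs = c(140, 9, 11, 1, 0) / 161,
      case_template = validation_case_template(),
      control_template = validation_control_template())
  )
}

#' Simulate a patient cohort from a specification
#'
#' In `exact_marginal` mode every patient's predictor flags come from the
#' spec's joint template (one patient per template row), so each
#' predictor's 2x2 table against GHD status is exact and the control
#' profiles never satisfy the prediction rule; the seed drives only
#' demographics, auxology and GH peak values. In `stochastic` mode case
#' status is Bernoulli with the spec prevalence and each patient's flag
#' profile is resampled from the matching template stratum, preserving the
#' between-flag dependence while letting all margins fluctuate. GH peaks
#' are drawn strictly below the era cut-off for cases and with at least
#' one peak at or above it for controls (placeholders with the correct
#' ascertainment behaviour, not a secretion model). Patients lighter than
#' 10 kg receive a single test arm. Every simulated patient satisfies at
#' least one GHST eligibility criterion (low height velocity is filled in
#' where the height deficit alone does not qualify).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same seed yields a byte-identical cohort.
#' @param n Cohort size for stochastic mode (defaults to `spec$n`).
#' @param mode `"exact_marginal"` or `"stochastic"` (defaults to
#'   `spec$mode`).
#' @return A `ghd_cohort` data.frame, ascertained (`ghd_status` filled).
#' @export
simulate_cohort <- function(spec, seed = 1L, n = spec$n,
                            mode = spec$mode) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode, c("exact_marginal", "stochastic"))
  set.seed(seed)

  if (mode == "exact_marginal") {
    if (n != spec$n) {
      stop("exact_marginal mode reproduces the spec margins and requires ",
           "n = ", spec$n, call. = FALSE)
    }
    flags <- rbind(spec$case_template, spec$control_template)
    status <- c(rep("case", spec$n_case), rep("control", n - spec$n_case))
  } else {
    is_case <- stats::rbinom(n, 1, spec$prevalence) == 1
    pick <- function(tmpl, k) {
      tmpl[sample.int(nrow(tmpl), k, replace = TRUE), , drop = FALSE]
    }
    flags <- flag_template(n)
    if (any(is_case)) flags[is_case, ] <- pick(spec$case_template,
                                               sum(is_case))
    if (any(!is_case)) flags[!is_case, ] <- pick(spec$control_template,
                                                 sum(!is_case))
    status <- ifelse(is_case, "case", "control")
  }
  if (n == 0L) {
    return(structure(cbind(data.frame(patient_id = character(0),
                                      sex = character(0)),
                           flag_template(0)),
                     class = c("ghd_cohort", "data.frame")))
  }

  rnorm_med <- function(par, k) stats::rnorm(k, par[["median"]],
                                             par[["sd"]])
  age <- pmin(pmax(rnorm_med(spec$age, n), 0.25), 17.9)
  height <- rnorm_med(spec$height_sds, n)
  weight_sds <- rnorm_med(spec$weight_sds, n)
  bmi <- rnorm_med(spec$bmi_sds, n)
  igf1 <- ifelse(status == "case",
                 rnorm_med(spec$igf1_case, n),
                 rnorm_med(spec$igf1_control, n))
  sex <- ifelse(stats::runif(n) < spec$male_frac, "M", "F")
  pubertal <- sample.int(5L, n, replace = TRUE,
                         prob = spec$pubertal_probs)
  # crude weight-for-age so infants fall below the 10 kg single-test limit
  weight_kg <- round(pmax(3, 8 + 2 * (age - 2) + stats::rnorm(n, 0, 2)), 1)
  era <- sample(seq(spec$era_from, spec$era_to), n, replace = TRUE)

  peaks <- vapply(seq_len(n), function(i) {
    cut <- gh_cutoff(era[i])
    two <- weight_kg[i] >= 10
    if (status[i] == "case") {
      v <- stats::runif(if (two) 2 else 1, 0.05, cut * 0.97)
    } else {
      v <- stats::runif(1, cut * 1.03, 20)
      if (two) v <- c(v, stats::runif(1, 0.05, 20))
    }
    paste(formatC(v, digits = 2, format = "f"), collapse = ";")
  }, character(1))

  # guarantee GHST eligibility: fill in a low height velocity where the
  # height deficit alone does not qualify
  hv <- round(pmin(stats::rnorm(n, -2.6, 0.3), -2.05), 2)
  mpd <- flags$acth_deficiency %in% TRUE | flags$tsh_deficiency %in% TRUE |
    flags$prolactin_deficiency %in% TRUE |
    flags$central_diabetes_insipidus %in% TRUE

  cohort <- cbind(
    data.frame(patient_id = sprintf("%s_%04d", spec$name, seq_len(n)),
               sex = sex, age_years = round(age, 2), era = era,
               pubertal_stage = pubertal,
               height_sds = round(height, 2),
               weight_sds = round(weight_sds, 2),
               bmi_sds = round(bmi, 2),
               midparental_height_sds = NA_real_,
               height_velocity_sds = hv,
               delta_height_sds_1yr = NA_real_,
               weight_kg = weight_kg, gh_peaks = peaks,
               igf1_sds = round(igf1, 2),
               intracranial_lesion_signs = flags$sellar_tumor_surgery %in%
                 TRUE,
               mpd_signs = mpd,
               neonatal_ghd_signs = flags$neonatal_hypoglycemia %in% TRUE |
                 flags$neonatal_cholestasis %in% TRUE |
                 flags$neonatal_hypogenitalism %in% TRUE,
               stringsAsFactors = FALSE),
    flags)
  rownames(cohort) <- NULL
  cohort <- ascertain_cohort(cohort)
  if (!identical(cohort$ghd_status, status)) {
    stop("internal error: simulated GH peaks do not reproduce the ",
         "intended case status", call. = FALSE)
  }
  attr(cohort, "spec_name") <- spec$name
  attr(cohort, "seed") <- seed
  attr(cohort, "mode") <- mode
  class(cohort) <- c("ghd_cohort", "data.frame")
  cohort
}
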