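#' Assemble a raw clinical panel
#'
#' Container for the raw measurements from which the fifteen dichotomous
#' predictors are derived. All fields are optional; a missing input yields a
#' missing predictor flag downstream. Units are fixed: free T4 in ng/dl, TSH
#' in mIU/l, cortisol in ug/dl, glucose in mg/dl (days of life 3-28),
#' bilirubin fractions in the same unit as each other, penile length as SDS,
#' testis volume in ml, osmolarity in mosm/l, radiotherapy dose in Gy,
#' chemotherapy duration in months.
#'
#' @param free_t4_ng_dl,tsh_mIU_l,cortisol_ug_dl Numeric, basal values.
#' @param acth_status `"low_or_normal"`, `"high"` or `NA`.
#' @param prolactin_centile_flag `"below_p2_5"`, `"normal"` or `NA`.
#' @param plasma_glucose_mg_dl Neonatal plasma glucose (days 3-28 of life).
#' @param conjugated_bilirubin,total_bilirubin Numeric, jointly present or
#'   jointly missing.
#' @param penile_length_sds Numeric SDS.
#' @param cryptorchidism Logical.
#' @param testis_volume_ml Numeric.
#' @param urine_plasma_osm_ratio,plasma_osm_mosm_l Numeric, for central
#'   diabetes insipidus work-up.
#' @param glasgow_coma_scale Integer 3-15 (worst recorded, head trauma).
#' @param radiotherapy_dose_Gy Numeric >= 0; 0 means no cranial radiotherapy.
#' @param chemo_duration_months Numeric >= 0.
#' @param mri_findings Character subset of `"anterior_hypoplasia_or_aplasia"`,
#'   `"stalk_interrupted_or_hypoplastic"`, `"posterior_ectopic_or_absent"`.
#' @param midline_findings Character vector of named midline anomalies
#'   (empty vector = assessed, none found; `NA` = not assessed).
#' @param tumor_or_surgery_sellar `"yes"`, `"microadenoma_only"`, `"no"` or
#'   `NA`.
#' @param genetic `"familial_case"`, `"pathogenic_mutation"`, `"none"` or
#'   `NA`.
#' @param cns_infection_history Logical: documented meningitis,
#'   meningoencephalitis, encephalitis or pyogenic ventriculitis.
#' @return An object of class `raw_clinical_panel`.
#' @export
raw_clinical_panel <- function(free_t4_ng_dl = NA, tsh_mIU_l = NA,
                               cortisol_ug_dl = NA, acth_status = NA,
                               prolactin_centile_flag = NA,
                               plasma_glucose_mg_dl = NA,
                               conjugated_bilirubin = NA,
                               total_bilirubin = NA,
                               penile_length_sds = NA,
                               cryptorchidism = NA,
                               testis_volume_ml = NA,
                               urine_plasma_osm_ratio = NA,
                               plasma_osm_mosm_l = NA,
                               glasgow_coma_scale = NA,
                               radiotherapy_dose_Gy = NA,
                               chemo_duration_months = NA,
                               mri_findings = NA,
                               midline_findings = NA,
                               tumor_or_surgery_sellar = NA,
                               genetic = NA,
                               cns_infection_history = NA) {
  panel <- list(free_t4_ng_dl = free_t4_ng_dl, tsh_mIU_l = tsh_mIU_l,
                cortisol_ug_dl = cortisol_ug_dl, acth_status = acth_status,
                prolactin_centile_flag = prolactin_centile_flag,
                plasma_glucose_mg_dl = plasma_glucose_mg_dl,
                conjugated_bilirubin = conjugated_bilirubin,
                total_bilirubin = total_bilirubin,
                penile_length_sds = penile_length_sds,
                cryptorchidism = cryptorchidism,
                testis_volume_ml = testis_volume_ml,
                urine_plasma_osm_ratio = urine_plasma_osm_ratio,
                plasma_osm_mosm_l = plasma_osm_mosm_l,
                glasgow_coma_scale = glasgow_coma_scale,
                radiotherapy_dose_Gy = radiotherapy_dose_Gy,
                chemo_duration_months = chemo_duration_months,
                mri_findings = mri_findings,
                midline_findings = midline_findings,
                tumor_or_surgery_sellar = tumor_or_surgery_sellar,
                genetic = genetic,
                cns_infection_history = cns_infection_history)
  # concentrations and doses must be non-negative when present
  for (f in c("free_t4_ng_dl", "tsh_mIU_l", "cortisol_ug_dl",
              "plasma_glucose_mg_dl", "conjugated_bilirubin",
              "total_bilirubin", "testis_volume_ml", "plasma_osm_mosm_l",
              "radiotherapy_dose_Gy", "chemo_duration_months")) {
    v <- panel[[f]]
    if (!all(is.na(v)) && any(v < 0, na.rm = TRUE)) {
      stop("field '", f, "' must be non-negative", call. = FALSE)
    }
  }
  cb <- panel$conjugated_bilirubin; tb <- panel$total_bilirubin
  if (xor(all(is.na(cb)), all(is.na(tb)))) {
    stop("fields 'conjugated_bilirubin' and 'total_bilirubin' must be ",
         "jointly present or jointly missing", call. = FALSE)
  }
  gcs <- panel$glasgow_coma_scale
  if (!all(is.na(gcs)) && (gcs < 3 || gcs > 15)) {
    stop("field 'glasgow_coma_scale' must be between 3 and 15", call. = FALSE)
  }
  structure(panel, class = "raw_clinical_panel")
}

#' Derive the fifteen dichotomous predictors from raw measurements
#'
#' Applies the operational predictor definitions: each flag is `TRUE`,
#' `FALSE` or `NA` (missing). Missingness is first-class at this layer; the
#' clinical rule decides missing-value policy later. Key definitions:
#' pituitary dysgenesis requires at least two of the three MRI findings and
#' is `NA` whenever no MRI was performed; sellar tumor/surgery excludes
#' isolated pituitary microadenoma; TSH deficiency is age-dependent (TSH
#' <= 10 mIU/l under 2 months of age, <= 6.5 mIU/l thereafter, both with
#' free T4 < 0.8 ng/dl); neonatal hypogenitalism requires at least two of
#' micropenis (penile length SDS < -2.5), cryptorchidism and micro-orchidism
#' (testis volume < 1 ml); neonatal cholestasis is a conjugated/total
#' bilirubin ratio > 0.15; severe TBI is a Glasgow Coma Scale score <= 8;
#' cranial radiotherapy counts at >= 18 Gy; chemotherapy at >= 6 months.
#' All thresholds are strict as stated.
#'
#' @param panel A [raw_clinical_panel()].
#' @param age_years Age at evaluation in years.
#' @param mri_available Logical: was a hypothalamic-pituitary MRI performed?
#' @return A `predictor_profile`: named logical vector of length 15 (`NA` =
#'   missing) with attribute `mri_available`.
#' @export
derive_predictors <- function(panel, age_years, mri_available) {
  stopifnot(inherits(panel, "raw_clinical_panel"),
            is.numeric(age_years), age_years >= 0,
            is.logical(mri_available), length(mri_available) == 1L,
            !is.na(mri_available))
  p <- panel
  and3 <- function(...) {
    # three-valued conjunction: FALSE dominates NA
    vals <- c(...)
    if (any(vals %in% FALSE)) FALSE else if (any(is.na(vals))) NA else TRUE
  }

  # pituitary dysgenesis: >= 2 of the MRI triad, only when MRI performed
  dysgenesis <- if (!mri_available) {
    NA
  } else {
    triad <- c("anterior_hypoplasia_or_aplasia",
               "stalk_interrupted_or_hypoplastic",
               "posterior_ectopic_or_absent")
    f <- p$mri_findings
    if (all(is.na(f))) NA else sum(triad %in% f) >= 2L
  }

  midline <- if (all(is.na(p$midline_findings))) NA else
    length(p$midline_findings[!is.na(p$midline_findings) &
                              nzchar(p$midline_findings)]) > 0L

  tumor <- if (is.na(p$tumor_or_surgery_sellar)) NA else
    identical(p$tumor_or_surgery_sellar, "yes")  # microadenoma_only -> FALSE

  cns <- if (is.na(p$cns_infection_history)) NA else
    isTRUE(p$cns_infection_history)

  tbi <- if (all(is.na(p$glasgow_coma_scale))) NA else
    p$glasgow_coma_scale <= 8

  radio <- if (is.na(p$radiotherapy_dose_Gy)) NA else
    p$radiotherapy_dose_Gy >= 18

  chemo <- if (is.na(p$chemo_duration_months)) NA else
    p$chemo_duration_months >= 6

  genetic <- if (is.na(p$genetic)) NA else
    p$genetic %in% c("familial_case", "pathogenic_mutation")

  tsh_limit <- if (age_years < 2 / 12) 10 else 6.5
  tsh <- and3(if (is.na(p$free_t4_ng_dl)) NA else p$free_t4_ng_dl < 0.8,
              if (is.na(p$tsh_mIU_l)) NA else p$tsh_mIU_l <= tsh_limit)

  acth <- and3(if (is.na(p$cortisol_ug_dl)) NA else p$cortisol_ug_dl < 6.5,
               if (is.na(p$acth_status)) NA else
                 identical(p$acth_status, "low_or_normal"))

  prl <- if (is.na(p$prolactin_centile_flag)) NA else
    identical(p$prolactin_centile_flag, "below_p2_5")

  di <- and3(if (is.na(p$urine_plasma_osm_ratio)) NA else
               p$urine_plasma_osm_ratio < 1.5,
             if (is.na(p$plasma_osm_mosm_l)) NA else
               p$plasma_osm_mosm_l > 300)

  hypoglycemia <- if (is.na(p$plasma_glucose_mg_dl)) NA else
    p$plasma_glucose_mg_dl < 50

  cholestasis <- if (all(is.na(p$conjugated_bilirubin))) NA else {
    if (p$total_bilirubin == 0) NA else
      p$conjugated_bilirubin / p$total_bilirubin > 0.15
  }

  # hypogenitalism: >= 2 of micropenis, cryptorchidism, micro-orchidism;
  # decidable early when the known components already settle the count
  comp <- c(micropenis = if (is.na(p$penile_length_sds)) NA else
              p$penile_length_sds < -2.5,
            cryptorchidism = if (is.na(p$cryptorchidism)) NA else
              isTRUE(p$cryptorchidism),
            micro_orchidism = if (all(is.na(p$testis_volume_ml))) NA else
              p$testis_volume_ml < 1)
  n_true <- sum(comp, na.rm = TRUE)
  n_na <- sum(is.na(comp))
  hypogenitalism <- if (n_true >= 2L) TRUE else
    if (n_true + n_na < 2L) FALSE else NA

  flags <- c(pituitary_dysgenesis = dysgenesis,
             midline_abnormality = midline,
             sellar_tumor_surgery = tumor,
             cns_infection = cns,
             severe_tbi = tbi,
             cranial_radiotherapy_ge18Gy = radio,
             chemotherapy_ge6mo = chemo,
             genetic_ghd = genetic,
             tsh_deficiency = tsh,
             acth_deficiency = acth,
             prolactin_deficiency = prl,
             central_diabetes_insipidus = di,
             neonatal_hypoglycemia = hypoglycemia,
             neonatal_cholestasis = cholestasis,
             neonatal_hypogenitalism = hypogenitalism)
  predictor_profile(flags, mri_available = mri_available)
}

#' Construct a predictor profile
#'
#' @param flags Named logical vector covering all of [predictor_names()]
#'   (`NA` = missing). Extra names are rejected.
#' @param mri_available Logical; when `FALSE`, `pituitary_dysgenesis` is
#'   forced to missing.
#' @return Object of class `predictor_profile`.
#' @export
predictor_profile <- function(flags, mri_available) {
  nm <- predictor_names()
  if (!all(names(flags) %in% nm)) {
    stop("unknown predictor name(s): ",
         paste(setdiff(names(flags), nm), collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(rep(NA, length(nm)), nm)
  full[names(flags)] <- as.logical(flags)
  stopifnot(is.logical(mri_available), length(mri_available) == 1L,
            !is.na(mri_available))
  if (!mri_available && !is.na(full[["pituitary_dysgenesis"]])) {
    stop("pituitary_dysgenesis must be missing when no MRI was performed",
         call. = FALSE)
  }
  structure(full, mri_available = mri_available, class = "predictor_profile")
}

#' @export
print.predictor_profile <- function(x, ...) {
  cat("<predictor_profile> (MRI ",
      if (attr(x, "mri_available")) "performed" else "not performed", ")\n",
      sep = "")
  v <- ifelse(is.na(unclass(x)), "missing", ifelse(x, "yes", "no"))
  for (nm in names(v)) cat(sprintf("  %-28s %s\n", nm, v[[nm]]))
  invisible(x)
}
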