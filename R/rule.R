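#' Comorbidities that qualify under the third rule clause
#' @return Character vector of the six qualifying comorbidity predictors.
#' @export
rule_comorbidities <- function() {
  c("neonatal_hypoglycemia", "neonatal_hypogenitalism",
    "central_diabetes_insipidus", "midline_abnormality",
    "sellar_tumor_surgery", "cranial_radiotherapy_ge18Gy")
}

anterior_deficiencies <- function() {
  c("tsh_deficiency", "acth_deficiency", "prolactin_deficiency")
}

#' Apply the clinical prediction rule to one predictor profile
#'
#' The rule labels an eligible patient as GHD when any clause fires:
#' (1) pituitary dysgenesis on MRI; or (2) two or more anterior pituitary
#' hormone (TSH, ACTH or prolactin) deficiencies; or (3) exactly one such
#' deficiency together with at least one of: neonatal hypoglycemia or
#' hypogenitalism, central diabetes insipidus, craniofacial midline
#' abnormalities, (supra)sellar tumor/surgery, or cranial radiotherapy
#' >= 18 Gy. A missing flag never satisfies a clause (the rule minimises
#' false positives, so absence of documentation is treated as absence of
#' the finding). The rule is only validated for patients meeting the GHST
#' eligibility criteria and refuses to classify ineligible patients.
#'
#' @param profile A [predictor_profile()] or named logical vector covering
#'   the rule's inputs (`NA` = missing).
#' @param eligible Logical: did the patient meet the GHST criteria?
#' @return A `rule_decision`: list with `positive`, `fired_clause` (one of
#'   `"dysgenesis"`, `"two_plus_deficiencies"`,
#'   `"one_deficiency_plus_comorbidity"`, `"none"`),
#'   `qualifying_comorbidities` (character, non-empty only for the third
#'   clause) and `missing_policy_applied` (TRUE when a missing flag was
#'   treated as absent while evaluating the rule).
#' @examples
#' pr <- predictor_profile(c(pituitary_dysgenesis = TRUE),
#'                         mri_available = TRUE)
#' classify_rule(pr)
#' @export
classify_rule <- function(profile, eligible = TRUE) {
  if (!isTRUE(eligible)) {
    stop("the prediction rule applies only to patients meeting the GHST ",
         "eligibility criteria", call. = FALSE)
  }
  flags <- unclass(profile)[intersect(names(unclass(profile)),
                                      predictor_names())]
  get <- function(nm) if (nm %in% names(flags)) flags[[nm]] else NA
  sat <- function(nm) isTRUE(get(nm))  # missing never satisfies

  consulted <- c("pituitary_dysgenesis", anterior_deficiencies(),
                 rule_comorbidities())
  missing_applied <- any(vapply(consulted, function(nm) is.na(get(nm)),
                                logical(1)))

  n_def <- sum(vapply(anterior_deficiencies(), sat, logical(1)))
  comorb <- rule_comorbidities()[vapply(rule_comorbidities(), sat,
                                        logical(1))]

  if (sat("pituitary_dysgenesis")) {
    clause <- "dysgenesis"; qual <- character(0)
  } else if (n_def >= 2L) {
    clause <- "two_plus_deficiencies"; qual <- character(0)
  } else if (n_def == 1L && length(comorb) > 0L) {
    clause <- "one_deficiency_plus_comorbidity"; qual <- comorb
  } else {
    clause <- "none"; qual <- character(0)
  }
  structure(list(positive = clause != "none", fired_clause = clause,
                 qualifying_comorbidities = qual,
                 missing_policy_applied = missing_applied),
            class = "rule_decision")
}

#' @export
print.rule_decision <- function(x, ...) {
  cat("<rule_decision> ", if (x$positive) "GHD-positive" else "negative",
      " (clause: ", x$fired_clause, ")\n", sep = "")
  if (length(x$qualifying_comorbidities) > 0L) {
    cat("  qualifying comorbidities: ",
        paste(x$qualifying_comorbidities, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Apply the prediction rule to an ascertained cohort
#'
#' Screens every patient for GHST eligibility, classifies eligible patients
#' with [classify_rule()], and tallies the decisions against the
#' GHST-based status into a confusion matrix. Ineligible patients are
#' excluded and counted.
#'
#' @param cohort Ascertained cohort data.frame (predictor columns plus
#'   `ghd_status`).
#' @return List of class `rule_evaluation`: `decisions` (one row per
#'   eligible patient: `patient_id`, `positive`, `fired_clause`,
#'   `qualifying_comorbidities`, `missing_policy_applied`, `ghd_status`),
#'   `confusion` (a [confusion_matrix()]), `n_ineligible`.
#' @export
apply_rule_to_cohort <- function(cohort) {
  stopifnot(all(cohort$ghd_status %in% c("case", "control")))
  elig <- vapply(seq_len(nrow(cohort)), function(i) {
    check_eligibility(cohort[i, , drop = FALSE])$eligible
  }, logical(1))
  kept <- which(elig)
  rows <- lapply(kept, function(i) {
    flags <- vapply(predictor_names(), function(p) {
      v <- cohort[[p]][i]
      if (is.na(v)) NA else as.logical(v)
    }, logical(1))
    dec <- classify_rule(flags, eligible = TRUE)
    data.frame(patient_id = as.character(cohort$patient_id[i]),
               positive = dec$positive, fired_clause = dec$fired_clause,
               qualifying_comorbidities =
                 paste(dec$qualifying_comorbidities, collapse = ";"),
               missing_policy_applied = dec$missing_policy_applied,
               ghd_status = cohort$ghd_status[i])
  })
  decisions <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(patient_id = character(0), positive = logical(0),
               fired_clause = character(0),
               qualifying_comorbidities = character(0),
               missing_policy_applied = logical(0),
               ghd_status = character(0))
  cm <- confusion_matrix(
    tp = sum(decisions$positive & decisions$ghd_status == "case"),
    fp = sum(decisions$positive & decisions$ghd_status == "control"),
    fn = sum(!decisions$positive & decisions$ghd_status == "case"),
    tn = sum(!decisions$positive & decisions$ghd_status == "control"))
  structure(list(decisions = decisions, confusion = cm,
                 n_ineligible = sum(!elig)),
            class = "rule_evaluation")
}

#' @export
print.rule_evaluation <- function(x, ...) {
  cat("<rule_evaluation> ", nrow(x$decisions), " patients classified, ",
      x$n_ineligible, " ineligible excluded\n", sep = "")
  print(x$confusion)
  invisible(x)
}
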