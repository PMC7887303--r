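#' Build the model-building feature matrix from a cohort
#'
#' Converts the selected tri-state predictor columns into factors and adds
#' the derived anterior-deficiency count: the number of TSH, ACTH and
#' prolactin deficiencies, categorised as `"0"` (none), `"1"` (any one) or
#' `"2+"` (multiple pituitary hormone deficiency). The three individual
#' deficiency columns are absorbed into the count and dropped from the
#' matrix.
#'
#' @param cohort Ascertained cohort data.frame.
#' @param predictors Predictor columns to include (before collapsing the
#'   anterior deficiencies); defaults to all fifteen.
#' @param missing_policy `"absent"` counts a missing deficiency flag as no
#'   deficiency (conservative, the default); `"na"` propagates missingness
#'   to the count.
#' @return List with `x` (data.frame of factor features) and `y` (label
#'   factor `case`/`control`).
#' @export
feature_matrix <- function(cohort, predictors = predictor_names(),
                           missing_policy = c("absent", "na")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(all(cohort$ghd_status %in% c("case", "control")))
  def <- anterior_deficiencies()
  keep <- setdiff(intersect(predictors, predictor_names()), def)
  x <- as.data.frame(lapply(cohort[keep], function(v) {
    factor(ifelse(is.na(v), NA_character_, ifelse(v, "yes", "no")),
           levels = c("no", "yes"))
  }), optional = TRUE)
  if (any(def %in% predictors)) {
    # the count feature is defined over the whole trio: selecting any
    # anterior deficiency pulls in all three
    flags <- cohort[def]
    n_def <- rowSums(as.data.frame(lapply(flags, function(v) {
      as.integer(v %in% TRUE)
    })))
    if (missing_policy == "na") {
      any_na <- rowSums(as.data.frame(lapply(flags, is.na))) > 0
      # only indeterminate when the known flags cannot settle the category
      n_def[any_na & n_def < 2] <- NA_integer_
    }
    x$anterior_deficiency_count <-
      factor(ifelse(is.na(n_def), NA_character_,
                    ifelse(n_def >= 2, "2+", as.character(n_def))),
             levels = c("0", "1", "2+"))
  }
  list(x = x, y = factor(cohort$ghd_status, levels = c("case", "control")))
}
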