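cohort_schema_version <- 1L

cohort_required_columns <- function() {
  c("patient_id", "sex", "age_years", "era", "pubertal_stage",
    "height_sds", "weight_kg", "gh_peaks", "mri_available",
    predictor_names())
}

#' Write a cohort to CSV
#'
#' One row per patient; predictor flags encoded 0/1/NA, the GH peak list as
#' a semicolon-separated field, missing values as `NA`. The first line is a
#' schema-version comment checked by [read_cohort()].
#'
#' @param cohort A cohort data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (p in c(predictor_names(), "mri_available",
              "intracranial_lesion_signs", "mpd_signs",
              "neonatal_ghd_signs")) {
    if (p %in% names(out)) out[[p]] <- as.integer(out[[p]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ghd_cohort_schema: %d", cohort_schema_version), con)
  utils::write.csv(out, con, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Checks the schema-version header comment and the presence of every
#' required column; schema violations are reported with the offending
#' column name.
#'
#' @param path CSV file written by [write_cohort()] (or assembled to the
#'   same schema).
#' @return A `ghd_cohort` data.frame with logical predictor columns.
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^# ghd_cohort_schema: ([0-9]+)$", first))[[1]]
  if (length(m) != 2L) {
    stop("not a cohort CSV: missing schema header comment", call. = FALSE)
  }
  if (as.integer(m[2]) != cohort_schema_version) {
    stop("unsupported cohort schema version ", m[2], call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", na.strings = "NA",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_required_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (p in c(predictor_names(), "mri_available",
              "intracranial_lesion_signs", "mpd_signs",
              "neonatal_ghd_signs")) {
    if (p %in% names(df)) {
      bad <- !(df[[p]] %in% c(0L, 1L, NA))
      if (any(bad)) {
        stop("column '", p, "' must be coded 0/1/NA (row ",
             which(bad)[1], ")", call. = FALSE)
      }
      df[[p]] <- as.logical(df[[p]])
    }
  }
  class(df) <- c("ghd_cohort", "data.frame")
  df
}
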