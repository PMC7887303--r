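# Published per-predictor 2x2 counts (a = predictor+ case, b = predictor+
# control, c = predictor- case, d = predictor- control) and the point odds
# ratios printed alongside them. Dysgenesis counts refer to the
# MRI-assessed subset.
table3_counts <- function() {
  list(
    pituitary_dysgenesis        = list(cells = c(38, 0, 82, 98),   or = Inf),
    midline_abnormality         = list(cells = c(19, 17, 131, 603), or = 5.1),
    sellar_tumor_surgery        = list(cells = c(13, 3, 137, 617),  or = 19.5),
    cns_infection               = list(cells = c(0, 6, 150, 614),   or = 0.0),
    severe_tbi                  = list(cells = c(1, 2, 149, 618),   or = 2.1),
    cranial_radiotherapy_ge18Gy = list(cells = c(10, 10, 140, 610), or = 4.4),
    chemotherapy_ge6mo          = list(cells = c(10, 11, 140, 609), or = 4.0),
    genetic_ghd                 = list(cells = c(3, 1, 147, 619),   or = 12.6),
    tsh_deficiency              = list(cells = c(42, 1, 108, 619),  or = 240.7),
    acth_deficiency             = list(cells = c(32, 0, 118, 620),  or = Inf),
    prolactin_deficiency        = list(cells = c(3, 0, 147, 620),   or = Inf),
    central_diabetes_insipidus  = list(cells = c(17, 4, 133, 616),  or = 19.7),
    neonatal_hypoglycemia       = list(cells = c(18, 12, 132, 608), or = 6.9),
    neonatal_cholestasis        = list(cells = c(5, 4, 145, 616),   or = 5.3),
    neonatal_hypogenitalism     = list(cells = c(18, 8, 132, 612),  or = 10.4))
}

# Simulated cohorts are expensive enough to share across tests in a file.
derivation_cohort <- local({
  memo <- NULL
  function(seed = 101) {
    if (is.null(memo)) {
      memo <<- simulate_cohort(default_specs()$derivation_2004_2014,
                               seed = seed)
    }
    memo
  }
})

validation_cohort <- local({
  memo <- NULL
  function(seed = 202) {
    if (is.null(memo)) {
      memo <<- simulate_cohort(default_specs()$validation_2017_2019,
                               seed = seed)
    }
    memo
  }
})

# A profile with every flag set to a given value.
all_flags <- function(value = FALSE, mri = TRUE, ...) {
  flags <- stats::setNames(rep(value, length(predictor_names())),
                           predictor_names())
  over <- list(...)
  flags[names(over)] <- unlist(over)
  if (!mri) flags["pituitary_dysgenesis"] <- NA
  predictor_profile(flags, mri_available = mri)
}

# Random tri-state profile generator for property sweeps.
random_profile <- function() {
  vals <- sample(c(TRUE, FALSE, NA), length(predictor_names()),
                 replace = TRUE, prob = c(0.2, 0.6, 0.2))
  names(vals) <- predictor_names()
  mri <- sample(c(TRUE, FALSE), 1)
  if (!mri) vals["pituitary_dysgenesis"] <- NA
  predictor_profile(vals, mri_available = mri)
}
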