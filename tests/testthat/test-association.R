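test_that("odds ratio point estimates and zero-cell handling", {
  est <- odds_ratio(two_by_two(19, 17, 131, 603))
  expect_equal(round(est$or_point, 1), 5.1)
  expect_identical(est$method, "woolf_log")

  expect_equal(round(odds_ratio(two_by_two(42, 1, 108, 619))$or_point, 1),
               240.7)

  # predictor absent in all cases: OR 0 with a finite exact upper bound
  z <- odds_ratio(two_by_two(0, 6, 150, 614))
  expect_identical(z$or_point, 0)
  expect_identical(z$method, "exact_conditional")
  expect_identical(z$ci_low, 0)
  expect_true(is.finite(z$ci_high) && z$ci_high > 0)

  # predictor absent in all controls: OR infinity, finite lower bound
  inf <- odds_ratio(two_by_two(38, 0, 82, 98,
                               denominator_policy = "assessed_only"))
  expect_identical(inf$or_point, Inf)
  expect_true(is.finite(inf$ci_low) && inf$ci_low > 1)
  expect_identical(inf$ci_high, Inf)

  # balanced tables have OR exactly 1
  for (km in list(c(3, 10), c(7, 7), c(1, 25))) {
    est1 <- odds_ratio(two_by_two(km[1], km[1], km[2], km[2]))
    expect_equal(est1$or_point, 1)
  }

  expect_error(two_by_two(0, 0, 0, 0), "empty")
  expect_error(two_by_two(-1, 2, 3, 4), "non-negative")
  expect_error(odds_ratio(two_by_two(0, 6, 150, 614),
                          method = "woolf_log"), "zero cell")
})

test_that("odds ratio is transpose-consistent under label swap", {
  set.seed(9)
  for (i in 1:50) {
    cells <- sample(1:60, 4, replace = TRUE)
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    # swapping case/control columns replaces OR by its reciprocal
    t2 <- two_by_two(cells[2], cells[1], cells[4], cells[3])
    expect_equal(odds_ratio(t1)$or_point * odds_ratio(t2)$or_point, 1,
                 tolerance = 1e-12)
  }
})

test_that("exact conditional interval matches the enumeration-based tails", {
  # independent oracle: noncentral hypergeometric tail probability from an
  # explicit product-of-binomial-coefficients enumeration
  tail_ge <- function(psi, a, b, c, d) {
    r1 <- a + b; r2 <- c + d; k <- a + c
    xs <- max(0, k - r2):min(k, r1)
    w <- vapply(xs, function(x) choose(r1, x) * choose(r2, k - x) * psi^x,
                numeric(1))
    sum(w[xs >= a]) / sum(w)
  }
  tail_le <- function(psi, a, b, c, d) {
    r1 <- a + b; r2 <- c + d; k <- a + c
    xs <- max(0, k - r2):min(k, r1)
    w <- vapply(xs, function(x) choose(r1, x) * choose(r2, k - x) * psi^x,
                numeric(1))
    sum(w[xs <= a]) / sum(w)
  }
  set.seed(11)
  tried <- 0
  while (tried < 40) {
    cells <- sample(0:12, 4, replace = TRUE)
    if (sum(cells) == 0 || sum(cells) > 40) next
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    r1 <- a + b; r2 <- c + d; k <- a + c
    ci <- ghdrule:::exact_or_ci(a, b, c, d)
    if (a > max(0, k - r2)) {
      expect_equal(tail_ge(ci[1], a, b, c, d), 0.025, tolerance = 1e-6)
    } else {
      expect_identical(ci[1], 0)
    }
    if (a < min(k, r1)) {
      expect_equal(tail_le(ci[2], a, b, c, d), 0.025, tolerance = 1e-6)
    } else {
      expect_identical(ci[2], Inf)
    }
    tried <- tried + 1
  }
})

test_that("exact conditional interval agrees with fisher.test", {
  # fisher.test inverts the same conditional tails but with a coarser
  # root-search tolerance, so agreement is asserted on the log scale
  for (cells in list(c(38, 0, 82, 98), c(0, 6, 150, 614),
                     c(42, 1, 108, 619), c(19, 17, 131, 603),
                     c(3, 0, 147, 620), c(5, 4, 145, 616))) {
    mine <- ghdrule:::exact_or_ci(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$conf.int
    if (mine[1] > 0) {
      expect_lt(abs(log(mine[1] / ref[1])), 0.08)
    } else {
      expect_equal(ref[1], 0, tolerance = 1e-8)
    }
    if (is.finite(ref[2])) {
      expect_lt(abs(log(mine[2] / ref[2])), 0.08)
    } else {
      expect_identical(mine[2], Inf)
    }
  }
})

test_that("Pearson chi-squared association matches the direct formula", {
  # oracle: chi-squared from expected counts, computed longhand
  cells <- c(1, 2, 149, 618)
  m <- matrix(cells, 2, byrow = TRUE)
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  stat <- sum((m - expected)^2 / expected)
  p_oracle <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p_pkg <- suppressWarnings(chisq_association(two_by_two(1, 2, 149, 618)))
  expect_equal(p_pkg, p_oracle, tolerance = 1e-12)

  expect_lt(chisq_association(two_by_two(18, 12, 132, 608)), 1e-4)
  expect_identical(format_p(chisq_association(two_by_two(18, 12, 132, 608))),
                   "<0.0001")
  expect_equal(chisq_association(two_by_two(5, 5, 20, 20)), 1)
  expect_warning(chisq_association(two_by_two(0, 0, 10, 12)), "margin")
})

test_that("a-priori frequency table reports conditional GHD probabilities", {
  coh <- derivation_cohort()
  ap <- apriori_table(coh)
  overall <- ap[ap$predictor == "(overall)", ]
  expect_equal(overall$p_ghd, 150 / 770)

  apv <- apriori_table(validation_cohort())
  expect_equal(apv[apv$predictor == "(overall)", "p_ghd"], 36 / 161)

  # dysgenesis strata: yes-stratum is all cases, missing stratum counted
  dy <- ap[ap$predictor == "pituitary_dysgenesis", ]
  expect_equal(dy$n[dy$stratum == "yes"], 38)
  expect_equal(dy$p_ghd[dy$stratum == "yes"], 1)
  expect_equal(dy$n[dy$stratum == "missing"], 770 - 218)

  # a predictor with no missing values has an empty missing stratum
  ts <- ap[ap$predictor == "tsh_deficiency", ]
  expect_equal(ts$n[ts$stratum == "missing"], 0)
  expect_true(is.na(ts$p_ghd[ts$stratum == "missing"]))
})

test_that("continuous summaries report median and IQR per status group", {
  coh <- derivation_cohort()
  cs <- continuous_summary(coh, "height_sds")
  expect_identical(cs$group, c("total", "case", "control"))
  expect_equal(cs$n[1], 770)
  # generator calibration: total median near the published -2.51
  expect_lt(abs(cs$median[1] - (-2.51)), 0.15)

  one <- continuous_summary(
    data.frame(height_sds = -2.5, ghd_status = "case"), "height_sds")
  expect_equal(one$median[one$group == "case"], -2.5)
  expect_equal(one$q1[one$group == "case"], one$q3[one$group == "case"])
  expect_error(continuous_summary(coh, "no_such_column"), "no column")
})

test_that("association panel uses the MRI-assessed denominator for dysgenesis", {
  coh <- derivation_cohort()
  at <- association_table(coh)
  dy <- at[at$predictor == "pituitary_dysgenesis", ]
  expect_identical(dy$denominator_policy, "assessed_only")
  expect_equal(dy$a + dy$b + dy$c + dy$d, 218)
  others <- at[at$predictor != "pituitary_dysgenesis", ]
  expect_true(all(others$a + others$b + others$c + others$d == 770))
})

test_that("feature selection keeps strong predictors plus radiotherapy", {
  at <- association_table(derivation_cohort())
  sel <- select_predictors(at)
  expect_true(all(c("pituitary_dysgenesis", "tsh_deficiency",
                    "acth_deficiency", "central_diabetes_insipidus",
                    "cranial_radiotherapy_ge18Gy") %in% sel))
  expect_false(any(c("cns_infection", "severe_tbi", "chemotherapy_ge6mo",
                     "neonatal_cholestasis") %in% sel))
})
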