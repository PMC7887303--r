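#' Construct a confusion matrix
#'
#' @param tp,fp,fn,tn Non-negative counts; total must be positive.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("confusion-matrix counts must be non-negative", call. = FALSE)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
              dimnames = list(predicted = c("case", "control"),
                              truth = c("case", "control")))
  print(m)
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the score test; well-behaved at proportions near 0 and 1, where
#' the Wald interval collapses. Bounds are clamped to `[0, 1]`.
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, positive.
#' @param conf_level Confidence level, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' wilson_ci(61, 150)   # 0.331-0.487
#' wilson_ci(620, 620)  # lower bound 0.994
#' @export
wilson_ci <- function(successes, n, conf_level = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  pmin(pmax(c(centre - half, centre + half), 0), 1)
}

metric_entry <- function(num, den, conf_level) {
  if (is.na(den) || den == 0) {
    return(list(est = NA_real_, low = NA_real_, high = NA_real_))
  }
  ci <- wilson_ci(num, den, conf_level)
  list(est = num / den, low = ci[1], high = ci[2])
}

#' Diagnostic-performance report from a confusion matrix
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values, accuracy and F-measure (each with a Wilson score interval), the
#' positive likelihood ratio (`Inf` at specificity 1, formatted as
#' `">1,000"`), and the number needed to test, `1 / (PPV + NPV - 1)` --
#' the expected number of rule applications per net correct diagnosis.
#' Metrics whose denominator is zero are reported as `NA` (undefined), not
#' as 0.
#'
#' @param m A [confusion_matrix()].
#' @param conf_level Confidence level for the Wilson intervals.
#' @return Object of class `diagnostic_report`.
#' @examples
#' diagnostic_report(confusion_matrix(tp = 20, fp = 1, fn = 16, tn = 124))
#' @export
diagnostic_report <- function(m, conf_level = 0.95) {
  stopifnot(inherits(m, "confusion_matrix"))
  tp <- m$tp; fp <- m$fp; fn <- m$fn; tn <- m$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)

  sens <- metric_entry(tp, tp + fn, conf_level)
  spec <- metric_entry(tn, tn + fp, conf_level)
  ppv  <- metric_entry(tp, tp + fp, conf_level)
  npv  <- metric_entry(tn, tn + fn, conf_level)
  acc  <- metric_entry(tp + tn, total, conf_level)

  f_est <- if (is.na(ppv$est) || is.na(sens$est) ||
               (ppv$est + sens$est) == 0) NA_real_ else
    2 * ppv$est * sens$est / (ppv$est + sens$est)

  lr <- if (is.na(spec$est) || is.na(sens$est)) NA_real_ else
    if (spec$est == 1) Inf else sens$est / (1 - spec$est)
  lr_fmt <- if (is.na(lr)) NA_character_ else
    if (is.infinite(lr)) ">1,000" else formatC(lr, digits = 1,
                                               format = "f")

  nnt <- if (is.na(ppv$est) || is.na(npv$est) ||
             (ppv$est + npv$est - 1) <= 0) NA_real_ else
    1 / (ppv$est + npv$est - 1)
  # conservative interval from the component Wilson bounds
  nnt_ci <- if (is.na(nnt)) c(NA_real_, NA_real_) else {
    hi_den <- ppv$low + npv$low - 1
    c(1 / (ppv$high + npv$high - 1),
      if (hi_den > 0) 1 / hi_den else Inf)
  }

  structure(list(matrix = m, conf_level = conf_level,
                 sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, accuracy = acc,
                 f_measure = list(est = f_est),
                 lr_positive = lr, lr_positive_formatted = lr_fmt,
                 nnt = nnt, nnt_low = nnt_ci[1], nnt_high = nnt_ci[2]),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  pc <- function(e) {
    if (is.na(e$est)) return("undefined")
    sprintf("%.1f (%.1f-%.1f)", 100 * e$est, 100 * e$low, 100 * e$high)
  }
  cat("<diagnostic_report> (", 100 * x$conf_level, "% CI)\n", sep = "")
  cat(sprintf("  Specificity, %% (CI)  %s\n", pc(x$specificity)))
  cat(sprintf("  Sensitivity, %% (CI)  %s\n", pc(x$sensitivity)))
  cat(sprintf("  Positive PV, %% (CI)  %s\n", pc(x$ppv)))
  cat(sprintf("  Negative PV, %% (CI)  %s\n", pc(x$npv)))
  cat(sprintf("  Positive LR          %s\n",
              if (is.na(x$lr_positive)) "undefined" else
                x$lr_positive_formatted))
  cat(sprintf("  NNT (CI)             %s\n",
              if (is.na(x$nnt)) "undefined" else
                sprintf("%.2f (%.2f-%.2f)", x$nnt, x$nnt_low, x$nnt_high)))
  cat(sprintf("  Accuracy, %%          %s\n",
              if (is.na(x$accuracy$est)) "undefined" else
                sprintf("%.1f", 100 * x$accuracy$est)))
  cat(sprintf("  F-measure            %s\n",
              if (is.na(x$f_measure$est)) "undefined" else
                sprintf("%.3f", x$f_measure$est)))
  invisible(x)
}

#' Exact binomial significance of the rule's positive calls
#'
#' Under the null hypothesis that a positive rule call carries no
#' information, each positive call is a Bernoulli trial with success
#' probability equal to the cohort's pre-test GHD prior. The reported
#' p-value is the upper-tail exact binomial probability
#' `P(X >= positives_correct)` with `n = positives_total` trials.
#'
#' @param positives_correct Correct positive calls (true positives).
#' @param positives_total Total positive calls.
#' @param prior_p Pre-test probability of GHD, in (0, 1).
#' @return The exact upper-tail p-value.
#' @examples
#' binomial_significance(20, 21, 36 / 161)  # ~1.6e-12
#' @export
binomial_significance <- function(positives_correct, positives_total,
                                  prior_p) {
  if (!(prior_p > 0 && prior_p < 1)) {
    stop("prior_p must lie strictly between 0 and 1", call. = FALSE)
  }
  if (positives_correct < 0 || positives_correct > positives_total) {
    stop("positives_correct must lie in [0, positives_total]",
         call. = FALSE)
  }
  stats::pbinom(positives_correct - 1, positives_total, prior_p,
                lower.tail = FALSE)
}

#' Assess the three validation axes of the prediction rule
#'
#' Safety: the rule must keep type I error near zero, operationalised as a
#' specificity of at least `min_specificity` (default 0.99). Usefulness:
#' sensitivity above `min_sensitivity` (default 0.2), so the rule spares a
#' GHST in at least a fifth of true GHD cases. Significance: the exact
#' binomial p-value of the positive calls against the cohort prior must be
#' below `alpha` (default 1e-5).
#'
#' @param report A [diagnostic_report()].
#' @param prior_p Pre-test GHD probability of the evaluated cohort.
#' @param alpha Significance level, default 1e-5.
#' @param min_sensitivity Usefulness threshold, default 0.2 (exclusive).
#' @param min_specificity Safety threshold, default 0.99 (inclusive).
#' @return List with logical `safety`, `usefulness`, `significance` and the
#'   underlying `binomial_p`.
#' @export
validation_axes <- function(report, prior_p, alpha = 1e-5,
                            min_sensitivity = 0.2,
                            min_specificity = 0.99) {
  stopifnot(inherits(report, "diagnostic_report"))
  m <- report$matrix
  p <- if (m$tp + m$fp > 0) {
    binomial_significance(m$tp, m$tp + m$fp, prior_p)
  } else NA_real_
  list(safety = !is.na(report$specificity$est) &&
         report$specificity$est >= min_specificity,
       usefulness = !is.na(report$sensitivity$est) &&
         report$sensitivity$est > min_sensitivity,
       significance = !is.na(p) && p < alpha,
       binomial_p = p, alpha = alpha)
}
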