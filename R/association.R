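#' Build a 2x2 predictor-by-status contingency table
#'
#' Cell layout follows the exposure convention: `a` = predictor present in
#' cases, `b` = predictor present in controls, `c` = predictor absent in
#' cases, `d` = predictor absent in controls.
#'
#' @param a,b,c,d Non-negative integer counts, total > 0.
#' @param denominator_policy `"full_cohort"` (unassessed patients counted as
#'   predictor-absent) or `"assessed_only"` (table restricted to patients in
#'   whom the predictor could be evaluated, as for MRI-based dysgenesis).
#' @return Object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, denominator_policy = "full_cohort") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("all four cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  denominator_policy <- match.arg(denominator_policy,
                                  c("full_cohort", "assessed_only"))
  structure(list(a = a, b = b, c = c, d = d,
                 denominator_policy = denominator_policy),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(predictor = c("yes", "no"),
                              status = c("case", "control")))
  cat("<two_by_two> (", x$denominator_policy, ")\n", sep = "")
  print(m)
  invisible(x)
}

#' @export
as.matrix.two_by_two <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), 2,
         dimnames = list(predictor = c("yes", "no"),
                         status = c("case", "control")))
}

#' Odds ratio with confidence interval for a 2x2 table
#'
#' The point estimate is the cross-product ratio `ad/bc`. With all cells
#' positive the default interval is the Woolf logit interval; the Haldane
#' (+0.5) corrected logit and the exact conditional interval (inverting the
#' tails of the noncentral hypergeometric distribution of `a` given the
#' margins) are available. Zero-cell tables get a degenerate point estimate
#' (`Inf` when `b` or `c` is zero with `a, d > 0`; `0` when `a` or `d` is
#' zero) with the corresponding one-sided exact conditional bound.
#'
#' @param t A [two_by_two()].
#' @param method `"auto"` (Woolf for finite tables, exact conditional bounds
#'   at zero cells), `"woolf_log"`, `"haldane_corrected"` or
#'   `"exact_conditional"`.
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `or_estimate`: list with `or_point`, `ci_low`,
#'   `ci_high`, `method`, `p_value` (Pearson chi-squared).
#' @examples
#' odds_ratio(two_by_two(19, 17, 131, 603))  # OR 5.1
#' odds_ratio(two_by_two(42, 1, 108, 619))   # OR 240.7
#' @export
odds_ratio <- function(t, method = c("auto", "woolf_log",
                                     "haldane_corrected",
                                     "exact_conditional"),
                       conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  method <- match.arg(method)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  zero <- (a == 0 || b == 0 || c == 0 || d == 0)
  point <- if (b * c == 0) {
    if (a > 0 && d > 0) Inf else if (a == 0 || d == 0) 0 else NaN
  } else a * d / (b * c)
  used <- if (method == "auto") {
    if (zero) "exact_conditional" else "woolf_log"
  } else method

  ci <- switch(used,
    woolf_log = {
      if (zero) stop("Woolf interval undefined with a zero cell; use ",
                     "'haldane_corrected' or 'exact_conditional'",
                     call. = FALSE)
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
      exp(log(point) + c(-1, 1) * z * se)
    },
    haldane_corrected = {
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      aa <- a + 0.5; bb <- b + 0.5; cc <- c + 0.5; dd <- d + 0.5
      or2 <- aa * dd / (bb * cc)
      se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
      exp(log(or2) + c(-1, 1) * z * se)
    },
    exact_conditional = exact_or_ci(a, b, c, d, conf_level)
  )
  p <- suppressWarnings(chisq_association(t))
  structure(list(or_point = point, ci_low = ci[1], ci_high = ci[2],
                 method = used, p_value = p, conf_level = conf_level),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, digits = 1, ...) {
  fmt <- function(v) if (is.infinite(v)) "Inf" else
    formatC(v, digits = digits, format = "f")
  cat(sprintf("OR %s (%g%% CI %s-%s, %s), p %s\n", fmt(x$or_point),
              100 * x$conf_level, fmt(x$ci_low), fmt(x$ci_high), x$method,
              format_p(x$p_value)), sep = "")
  invisible(x)
}

# Noncentral hypergeometric pmf of X = cell a given all margins, odds psi.
# Support runs from max(0, k - r2) to min(k, r1) with r1 = a+b, r2 = c+d,
# k = a+c.
nchg_pmf <- function(psi, a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  lo <- max(0, k - r2); hi <- min(k, r1)
  x <- lo:hi
  lg <- lchoose(r1, x) + lchoose(r2, k - x) + x * log(psi)
  p <- exp(lg - max(lg))
  list(x = x, p = p / sum(p))
}

# Exact conditional CI by tail inversion; one-sided bound at a boundary
# table (matching the behaviour of the conditional exact test).
exact_or_ci <- function(a, b, c, d, conf_level = 0.95) {
  alpha <- (1 - conf_level) / 2
  r1 <- a + b; r2 <- c + d; k <- a + c
  lo_sup <- max(0, k - r2); hi_sup <- min(k, r1)
  upper_tail <- function(lpsi) {
    q <- nchg_pmf(exp(lpsi), a, b, c, d)
    sum(q$p[q$x >= a])
  }
  lower_tail <- function(lpsi) {
    q <- nchg_pmf(exp(lpsi), a, b, c, d)
    sum(q$p[q$x <= a])
  }
  lo <- if (a == lo_sup) 0 else
    exp(stats::uniroot(function(l) upper_tail(l) - alpha,
                       interval = c(-35, 35), tol = 1e-9)$root)
  hi <- if (a == hi_sup) Inf else
    exp(stats::uniroot(function(l) lower_tail(l) - alpha,
                       interval = c(-35, 35), tol = 1e-9)$root)
  c(lo, hi)
}

#' Pearson chi-squared association p-value for a 2x2 table
#'
#' Uncorrected Pearson chi-squared test on 1 degree of freedom. A table
#' with a zero margin has no defined statistic and returns `NA` with a
#' warning.
#'
#' @param t A [two_by_two()].
#' @return The p-value (numeric scalar, possibly `NA`).
#' @export
chisq_association <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  m <- as.matrix(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin: chi-squared statistic undefined", call. = FALSE)
    return(NA_real_)
  }
  suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
}

#' Format a p-value the way association panels print it
#'
#' Values below 1e-4 are floored to the string `"<0.0001"`; raw values are
#' retained by the caller.
#'
#' @param p Numeric p-value.
#' @return Character scalar.
#' @export
format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 1e-4) "<0.0001" else formatC(p, digits = 4, format = "f")
}

#' Per-predictor frequency table with a-priori GHD probabilities
#'
#' For every predictor and stratum (yes / no / missing) reports patient
#' counts, case counts and the conditional probability of GHD; the overall
#' pre-test prior is included as the first row.
#'
#' @param cohort An ascertained cohort data.frame.
#' @return A data.frame with columns `predictor`, `stratum`, `n`, `n_case`,
#'   `p_ghd`.
#' @export
apriori_table <- function(cohort) {
  stopifnot(all(cohort$ghd_status %in% c("case", "control")))
  case <- cohort$ghd_status == "case"
  rows <- list(data.frame(predictor = "(overall)", stratum = "all",
                          n = nrow(cohort), n_case = sum(case),
                          p_ghd = if (nrow(cohort) > 0)
                            sum(case) / nrow(cohort) else NA_real_))
  for (pred in predictor_names()) {
    v <- cohort[[pred]]
    for (s in c("yes", "no", "missing")) {
      idx <- switch(s, yes = which(v %in% TRUE), no = which(v %in% FALSE),
                    missing = which(is.na(v)))
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = pred, stratum = s, n = length(idx),
        n_case = sum(case[idx]),
        p_ghd = if (length(idx) > 0) sum(case[idx]) / length(idx) else
          NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Median and interquartile range of a continuous variable by GHD status
#'
#' @param cohort An ascertained cohort data.frame.
#' @param variable Name of a numeric column.
#' @return data.frame with rows total/case/control and columns `n`,
#'   `median`, `q1`, `q3`.
#' @export
continuous_summary <- function(cohort, variable) {
  v <- cohort[[variable]]
  if (is.null(v)) stop("no column '", variable, "' in cohort", call. = FALSE)
  stopifnot(is.numeric(v))
  one <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(n = 0, median = NA, q1 = NA, q3 = NA))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
  }
  out <- rbind(total = one(v),
               case = one(v[cohort$ghd_status == "case"]),
               control = one(v[cohort$ghd_status == "control"]))
  data.frame(group = rownames(out), out, row.names = NULL)
}

#' Count a predictor against GHD status into a 2x2 table
#'
#' Under the `"full_cohort"` policy, patients with a missing flag count as
#' predictor-absent (no documented exposure); under `"assessed_only"` the
#' table is restricted to patients with a non-missing flag.
#'
#' @param cohort Ascertained cohort data.frame.
#' @param predictor Predictor column name.
#' @param denominator_policy See [two_by_two()].
#' @return A [two_by_two()].
#' @export
count_predictor <- function(cohort, predictor,
                            denominator_policy = "full_cohort") {
  v <- cohort[[predictor]]
  if (is.null(v)) stop("no column '", predictor, "' in cohort",
                       call. = FALSE)
  case <- cohort$ghd_status == "case"
  if (denominator_policy == "assessed_only") {
    keep <- !is.na(v)
    v <- v[keep]; case <- case[keep]
  } else {
    v[is.na(v)] <- FALSE
  }
  two_by_two(a = sum(v & case), b = sum(v & !case),
             c = sum(!v & case), d = sum(!v & !case),
             denominator_policy = denominator_policy)
}

#' Association panel over all fifteen predictors
#'
#' Reproduces the structure of a predictor-by-status association table:
#' per-predictor counts, odds ratio with confidence interval, and Pearson
#' chi-squared p-value. Pituitary dysgenesis (MRI-defined) uses the
#' MRI-assessed subset as denominator; all other predictors use the full
#' cohort.
#'
#' @param cohort Ascertained cohort data.frame.
#' @param method CI method passed to [odds_ratio()].
#' @param conf_level Confidence level.
#' @return data.frame of class `ghd_assoc_table` with one row per
#'   predictor: counts `a`, `b`, `c`, `d`, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `p_formatted`, `denominator_policy`.
#' @export
association_table <- function(cohort, method = "auto", conf_level = 0.95) {
  rows <- lapply(predictor_names(), function(pred) {
    pol <- if (pred == "pituitary_dysgenesis") "assessed_only" else
      "full_cohort"
    t <- count_predictor(cohort, pred, pol)
    est <- odds_ratio(t, method = method, conf_level = conf_level)
    data.frame(predictor = pred, a = t$a, b = t$b, c = t$c, d = t$d,
               or = est$or_point, ci_low = est$ci_low,
               ci_high = est$ci_high, ci_method = est$method,
               p_value = est$p_value,
               p_formatted = format_p(est$p_value),
               denominator_policy = pol)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ghd_assoc_table", "data.frame")
  out
}

#' Select predictors for model building from an association panel
#'
#' Keeps predictors whose odds ratio exceeds `or_min` with p-value below
#' `p_max`, plus any predictors forced in on clinical grounds (cranial
#' radiotherapy is retained by default despite OR < 5 because of its
#' clinical relevance).
#'
#' @param assoc A [association_table()] result.
#' @param or_min Minimum odds ratio (exclusive), default 5.
#' @param p_max Maximum p-value (exclusive), default 1e-4.
#' @param force Character vector of predictors always retained.
#' @return Character vector of selected predictor names.
#' @export
select_predictors <- function(assoc, or_min = 5, p_max = 1e-4,
                              force = "cranial_radiotherapy_ge18Gy") {
  stat <- assoc$predictor[!is.na(assoc$or) & assoc$or > or_min &
                          !is.na(assoc$p_value) & assoc$p_value < p_max]
  unique(c(stat, intersect(force, assoc$predictor)))
}
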