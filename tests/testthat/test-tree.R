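toy_features <- function() {
  # 8-row fixture with a 3-level nominal attribute and a binary one
  data.frame(
    color = factor(c("r", "r", "g", "g", "b", "b", "b", "r")),
    big = factor(c("yes", "yes", "no", "no", "yes", "no", "no", "yes")))
}
toy_labels <- function() {
  factor(c("case", "case", "control", "control", "case", "control",
           "control", "case"), levels = c("case", "control"))
}

test_that("entropy follows -sum p log2 p", {
  expect_equal(entropy(c(1, 1)), 1)
  expect_equal(entropy(c(5, 0)), 0)
  expect_equal(entropy(c(9)), 0)
  # direct evaluation oracle for the cohort-level class distribution
  p <- 150 / 770
  expect_equal(entropy(c(150, 620)), -p * log2(p) - (1 - p) * log2(1 - p))
  expect_equal(round(entropy(c(150, 620)), 3), 0.711)
  expect_error(entropy(c(0, 0)), "positive")
  expect_error(entropy(c(-1, 2)), "non-negative")
})

test_that("gain ratio normalises information gain by split information", {
  # perfectly separating balanced binary split: gain = split info = 1 bit
  y <- factor(rep(c("case", "control"), each = 4))
  s <- factor(rep(c("l", "r"), each = 4))
  expect_equal(gain_ratio(y, s), 1)

  # children with the parent's class mix carry no information
  s0 <- factor(rep(c("l", "r"), 4))
  expect_equal(gain_ratio(y, s0), 0)

  # three-way nominal split on the 8-row fixture vs the longhand formula
  x <- toy_features(); yl <- toy_labels()
  h <- function(k) { p <- k / sum(k); p <- p[p > 0]; -sum(p * log2(p)) }
  parent <- h(c(4, 4))
  child <- (3 / 8) * h(c(3, 0)) + (2 / 8) * h(c(0, 2)) + (3 / 8) * h(c(1, 2))
  split_info <- h(c(3, 2, 3))
  expect_equal(gain_ratio(yl, x$color), (parent - child) / split_info)

  # a single-part split is invalid, not divide-by-zero
  expect_true(is.na(gain_ratio(yl, factor(rep("a", 8)))))
  # missing rows are excluded from the computation
  s_na <- factor(c("l", "l", "r", "r", NA, NA, NA, NA))
  expect_equal(gain_ratio(yl, s_na), 1)
})

test_that("tree induction picks the best split and respects stopping rules", {
  # single-class data collapses to one leaf
  x <- data.frame(f = factor(c("a", "b", "a")))
  t1 <- fit_tree(x, factor(rep("case", 3)))
  expect_true(t1$root$leaf)
  expect_identical(t1$root$majority, "case")

  expect_error(fit_tree(data.frame(), factor(character(0))), "non-empty")

  # on the toy fixture, 'big' separates perfectly and must win the root
  tt <- fit_tree(toy_features(), toy_labels(), min_records = 1)
  expect_identical(tt$root$feature, "big")
  expect_identical(sort(unname(predict_tree(tt, toy_features()))),
                   sort(as.character(toy_labels())))
})

test_that("chosen root attains the brute-force maximal gain ratio", {
  set.seed(31)
  brute_best <- function(x, y) {
    q <- vapply(x, function(col) {
      g <- gain_ratio(y, col)
      if (is.na(g)) -Inf else g
    }, numeric(1))
    max(q)
  }
  for (i in 1:60) {
    n <- sample(4:6, 1); p <- sample(2:3, 1)
    x <- as.data.frame(replicate(p, factor(sample(c("a", "b"), n,
                                                  replace = TRUE)),
                                 simplify = FALSE))
    names(x) <- paste0("f", seq_len(p))
    y <- factor(sample(c("case", "control"), n, replace = TRUE),
                levels = c("case", "control"))
    fit <- fit_tree(x, y, min_records = 1)
    best <- brute_best(x, y)
    if (!fit$root$leaf) {
      expect_equal(gain_ratio(y, x[[fit$root$feature]]), best,
                   tolerance = 1e-12)
    } else {
      # a leaf is only allowed when no split has positive quality or the
      # data are too small/pure to split
      expect_true(best <= 1e-12 || length(y) < 2 ||
                  length(unique(y)) < 2)
    }
  }
})

test_that("refitting on permuted rows yields an identical tree", {
  coh <- derivation_cohort()
  fm <- feature_matrix(coh)
  t1 <- fit_tree(fm$x, fm$y)
  set.seed(5)
  perm <- sample(nrow(fm$x))
  t2 <- fit_tree(fm$x[perm, , drop = FALSE], fm$y[perm])
  strip <- function(node) {
    node$counts <- sort(node$counts)
    if (!node$leaf) node$children <- lapply(node$children, strip)
    node
  }
  expect_identical(strip(t1$root), strip(t2$root))
})

test_that("class counts are conserved down every path", {
  coh <- derivation_cohort()
  fm <- feature_matrix(coh)
  tr <- fit_tree(fm$x, fm$y)
  check <- function(node) {
    if (node$leaf) return(invisible())
    kid_sum <- Reduce(`+`, lapply(node$children, `[[`, "counts"))
    expect_equal(kid_sum, node$counts)
    expect_gte(length(node$children), 2L)
    for (ch in node$children) {
      expect_gte(ch$n, tr$min_records)
      check(ch)
    }
  }
  check(tr$root)
  expect_equal(tr$root$n, 770)
})

test_that("a dysgenesis-only signal produces a pure case branch", {
  # predictor present only among cases, as in the published counts
  n_case <- 30; n_ctrl <- 70
  x <- data.frame(pituitary_dysgenesis = factor(
    c(rep("yes", 12), rep("no", n_case - 12), rep("no", n_ctrl)),
    levels = c("no", "yes")))
  y <- factor(c(rep("case", n_case), rep("control", n_ctrl)),
              levels = c("case", "control"))
  tr <- fit_tree(x, y)
  expect_identical(tr$root$feature, "pituitary_dysgenesis")
  leaf <- tr$root$children[["yes"]]
  expect_true(leaf$leaf)
  expect_identical(leaf$majority, "case")
  expect_equal(sum(leaf$counts > 0), 1L)
})

test_that("prediction routes missing values to the largest child", {
  x <- data.frame(f = factor(c(rep("yes", 3), rep("no", 7)),
                             levels = c("no", "yes")))
  y <- factor(c(rep("case", 3), rep("control", 7)),
              levels = c("case", "control"))
  tr <- fit_tree(x, y)
  expect_identical(tr$root$default_child, "no")
  pred <- predict_tree(tr, data.frame(f = factor(c("yes", "no", NA),
                                                 levels = c("no", "yes"))))
  expect_identical(pred, c("case", "control", "control"))
})

test_that("predicted label agrees with a hand trace of a small tree", {
  x <- data.frame(
    a = factor(c("y", "y", "n", "n", "n", "n"), levels = c("n", "y")),
    b = factor(c("n", "n", "y", "y", "n", "n"), levels = c("n", "y")))
  y <- factor(c("case", "case", "case", "case", "control", "control"),
              levels = c("case", "control"))
  tr <- fit_tree(x, y, min_records = 1)
  # hand trace: a=y -> case; a=n & b=y -> case; a=n & b=n -> control
  grid <- data.frame(a = factor(c("y", "n", "n"), levels = c("n", "y")),
                     b = factor(c("n", "y", "n"), levels = c("n", "y")))
  expect_identical(predict_tree(tr, grid), c("case", "case", "control"))
})

test_that("false-positive branch pruning trades sensitivity for specificity", {
  coh <- derivation_cohort()
  fm <- feature_matrix(coh)
  tr <- fit_tree(fm$x, fm$y)
  conf <- function(tree) {
    pred <- predict_tree(tree, fm$x)
    c(tp = sum(pred == "case" & fm$y == "case"),
      fp = sum(pred == "case" & fm$y == "control"),
      fn = sum(pred == "control" & fm$y == "case"),
      tn = sum(pred == "control" & fm$y == "control"))
  }
  before <- conf(tr)
  pruned <- prune_fp_branch(tr, fm$x, fm$y)
  after <- conf(pruned)
  spec_before <- before["tn"] / (before["tn"] + before["fp"])
  spec_after <- after["tn"] / (after["tn"] + after["fp"])
  sens_before <- before["tp"] / (before["tp"] + before["fn"])
  sens_after <- after["tp"] / (after["tp"] + after["fn"])
  expect_gte(spec_after, spec_before)
  expect_lte(sens_after, sens_before)
  expect_lt(after["fp"], before["fp"])

  # a tree with no false positives is returned unchanged
  again <- prune_fp_branch(pruned, fm$x, fm$y)
  while (conf(again)["fp"] > 0) again <- prune_fp_branch(again, fm$x, fm$y)
  expect_identical(prune_fp_branch(again, fm$x, fm$y), again)
})

test_that("pruning collapses a single offending branch to zero FPs", {
  x <- data.frame(f = factor(c(rep("yes", 4), rep("no", 8)),
                             levels = c("no", "yes")))
  y <- factor(c(rep("case", 3), "control", rep("control", 8)),
              levels = c("case", "control"))
  tr <- fit_tree(x, y)
  pred <- predict_tree(tr, x)
  expect_equal(sum(pred == "case" & y == "control"), 1)
  pr <- prune_fp_branch(tr, x, y)
  pred2 <- predict_tree(pr, x)
  expect_equal(sum(pred2 == "case" & y == "control"), 0)
})

test_that("stratified cross-validation reports dispersion of the metrics", {
  coh <- derivation_cohort()
  fm <- feature_matrix(coh)
  cv <- cv_tree(fm$x, fm$y, reps = 5, seed = 3)
  expect_equal(nrow(cv$per_rep), 5)
  expect_true(all(c("sensitivity", "specificity", "accuracy") %in%
                  cv$summary$metric))
  expect_true(all(is.finite(cv$summary$mean)))
  expect_true(all(cv$per_rep$specificity > 0.9))  # high-specificity regime
})
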