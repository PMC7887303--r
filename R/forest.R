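#' Tree-ensemble feature relevance
#'
#' Fits an ensemble of gain-ratio trees on bootstrap resamples with a
#' random feature subset considered at every node, and ranks features by
#' how often, and how close to the root, the ensemble splits on them.
#' The importance score of a feature is the sum over all its split
#' occurrences of `1 / (1 + depth)`; split counts at depths 0-2 are also
#' reported separately. The forest is used only for feature relevance, not
#' for prediction.
#'
#' @param x data.frame of factor features.
#' @param y Label factor (`case`/`control`).
#' @param n_trees Number of trees, default 100.
#' @param mtry Features considered per node; default `ceiling(sqrt(p))`.
#' @param min_records Minimum records per node, default 2.
#' @param seed Integer seed; the report is reproducible given the seed.
#' @return Object of class `ghd_importance`: data.frame with columns
#'   `feature`, `n_splits`, `level0`, `level1`, `level2`, `score`,
#'   `rank`, sorted by decreasing score, with the ensemble parameters as
#'   attributes.
#' @export
fit_forest <- function(x, y, n_trees = 100L, mtry = NULL,
                       min_records = 2L, seed = 1L) {
  stopifnot(is.data.frame(x), nrow(x) >= 10L)
  y <- factor(y)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  feats <- names(x)
  zero <- stats::setNames(numeric(p), feats)
  tally <- list(n = zero, l0 = zero, l1 = zero, l2 = zero, score = zero)

  if (nlevels(droplevels(y)) < 2L) {
    warning("single-class data: all importances are zero", call. = FALSE)
  } else {
    set.seed(seed)
    n <- nrow(x)
    for (b in seq_len(n_trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      fit <- fit_tree(x[boot, , drop = FALSE], y[boot],
                      min_records = min_records, mtry = mtry)
      walk <- function(node, depth) {
        if (node$leaf) return(invisible())
        f <- node$feature
        tally$n[f] <<- tally$n[f] + 1
        if (depth <= 2L) {
          key <- paste0("l", depth)
          tally[[key]][f] <<- tally[[key]][f] + 1
        }
        tally$score[f] <<- tally$score[f] + 1 / (1 + depth)
        for (ch in node$children) walk(ch, depth + 1L)
      }
      walk(fit$root, 0L)
    }
  }
  out <- data.frame(feature = feats, n_splits = tally$n,
                    level0 = tally$l0, level1 = tally$l1,
                    level2 = tally$l2, score = tally$score,
                    row.names = NULL)
  out <- out[order(-out$score, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "params") <- list(n_trees = n_trees, mtry = mtry,
                              bootstrap = TRUE, min_records = min_records,
                              seed = seed)
  class(out) <- c("ghd_importance", "data.frame")
  out
}

#' @export
print.ghd_importance <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<ghd_importance> %d trees, mtry=%d, seed=%d\n",
              p$n_trees, p$mtry, p$seed))
  print.data.frame(x, digits = 3)
  invisible(x)
}
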