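#' Shannon entropy of a class-count vector
#'
#' @param class_counts Non-negative counts, total > 0.
#' @return Entropy in bits.
#' @examples
#' entropy(c(1, 1))      # 1 bit
#' entropy(c(150, 620))  # ~0.711 bits
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) == 0) {
    stop("class counts must be non-negative with positive total",
         call. = FALSE)
  }
  p <- class_counts / sum(class_counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Gini impurity, offered as an alternative split quality measure.
gini_impurity <- function(class_counts) {
  p <- class_counts / sum(class_counts)
  1 - sum(p^2)
}

#' Gain ratio of a candidate categorical split
#'
#' Information gain of the partition divided by its split information (the
#' intrinsic entropy of the partition sizes). Rows with a missing split
#' value are excluded from the computation. A split that produces fewer
#' than two non-empty parts, or has zero split information, is invalid and
#' yields `NA`.
#'
#' @param labels Factor (or vector) of class labels.
#' @param split Factor (or vector) partitioning the rows; `NA` = missing.
#' @param quality `"gain_ratio"` (default) or `"gini"` (mean impurity
#'   decrease, unnormalized).
#' @return Numeric scalar, or `NA_real_` for an invalid split.
#' @export
gain_ratio <- function(labels, split, quality = "gain_ratio") {
  keep <- !is.na(split)
  labels <- factor(labels[keep])
  split <- factor(as.character(split[keep]))
  if (length(labels) == 0L) return(NA_real_)
  sizes <- table(split)
  sizes <- sizes[sizes > 0]
  if (length(sizes) < 2L) return(NA_real_)
  parent_counts <- table(labels)
  n <- sum(parent_counts)
  imp <- if (quality == "gini") gini_impurity else entropy
  child_term <- sum(vapply(names(sizes), function(lev) {
    idx <- split == lev
    sizes[[lev]] / n * imp(table(labels[idx]))
  }, numeric(1)))
  gain <- imp(parent_counts) - child_term
  if (quality == "gini") return(gain)
  split_info <- entropy(as.numeric(sizes))
  if (split_info == 0) return(NA_real_)
  gain / split_info
}

#' Fit a gain-ratio decision tree
#'
#' Greedy recursive partitioning in the C4.5 family: multiway nominal
#' splits on categorical features, split quality measured by gain ratio
#' (optionally Gini), no post-pruning, and a minimum number of records per
#' node (default 2). Candidate splits leaving any non-empty child below
#' `min_records` are rejected. Rows missing the chosen split attribute are
#' excluded from that split's evaluation and routed to the largest child.
#' Ties between equally good splits are broken by the lowest column index,
#' making the fit deterministic and invariant to row order.
#'
#' @param x data.frame of factor features (`NA` = missing).
#' @param y Factor of labels with levels `case`/`control` (any two-level
#'   factor works; the first level sorted is used consistently).
#' @param min_records Minimum records per node, default 2.
#' @param quality `"gain_ratio"` or `"gini"`.
#' @param mtry If non-NULL, the number of features sampled (without
#'   replacement) as candidates at each node; used by [fit_forest()].
#' @param max_depth Optional depth cap.
#' @return Object of class `ghd_tree`.
#' @export
fit_tree <- function(x, y, min_records = 2L, quality = "gain_ratio",
                     mtry = NULL, max_depth = Inf) {
  if (!is.data.frame(x) || nrow(x) == 0L || ncol(x) == 0L) {
    stop("x must be a non-empty data.frame of features", call. = FALSE)
  }
  stopifnot(nrow(x) == length(y))
  y <- factor(y)
  classes <- levels(y)
  x <- as.data.frame(lapply(x, function(col) factor(as.character(col))),
                     stringsAsFactors = TRUE, optional = TRUE)
  node <- grow_node(x, y, idx = seq_len(nrow(x)), classes = classes,
                    min_records = min_records, quality = quality,
                    mtry = mtry, depth = 0L, max_depth = max_depth)
  structure(list(root = node, classes = classes, features = names(x),
                 min_records = min_records, quality = quality),
            class = "ghd_tree")
}

grow_node <- function(x, y, idx, classes, min_records, quality, mtry,
                      depth, max_depth) {
  counts <- table(factor(y[idx], levels = classes))
  maj <- majority_label(counts, classes)
  leaf <- list(leaf = TRUE, n = length(idx),
               counts = as.vector(counts), majority = maj)
  if (length(idx) < 2L * min_records || depth >= max_depth ||
      sum(counts > 0) < 2L) {
    return(leaf)
  }
  cand <- seq_along(x)
  if (!is.null(mtry) && mtry < length(cand)) {
    cand <- sort(sample(cand, mtry))
  }
  best_j <- NA_integer_; best_q <- -Inf
  for (j in cand) {
    v <- x[[j]][idx]
    keep <- !is.na(v)
    if (!any(keep)) next
    sizes <- table(droplevels(v[keep]))
    sizes <- sizes[sizes > 0]
    if (length(sizes) < 2L || any(sizes < min_records)) next
    q <- gain_ratio(y[idx], v, quality = quality)
    if (!is.na(q) && q > best_q + 1e-12) { best_q <- q; best_j <- j }
  }
  if (is.na(best_j) || best_q <= 1e-12) return(leaf)

  feat <- names(x)[best_j]
  v <- x[[best_j]][idx]
  levs <- names(sort(table(droplevels(v[!is.na(v)])), decreasing = TRUE))
  # largest child first; ties by level order from sort() are stable on names
  default_child <- levs[1L]
  parts <- lapply(levs, function(lev) idx[which(v %in% lev)])
  names(parts) <- levs
  # missing rows travel with the largest child so counts stay conserved
  miss <- idx[is.na(v)]
  if (length(miss) > 0L) {
    parts[[default_child]] <- sort(c(parts[[default_child]], miss))
  }
  children <- lapply(parts, function(sub) {
    grow_node(x, y, sub, classes, min_records, quality, mtry,
              depth + 1L, max_depth)
  })
  list(leaf = FALSE, n = length(idx), counts = as.vector(counts),
       majority = maj, feature = feat, children = children,
       default_child = default_child, quality = best_q)
}

majority_label <- function(counts, classes) {
  # deterministic tie-break: prefer "control" (the safe label) if present,
  # otherwise the first class level
  top <- which(counts == max(counts))
  if (length(top) > 1L && "control" %in% classes[top]) return("control")
  classes[top[1L]]
}

#' Predict labels from a fitted tree
#'
#' Each record walks from the root; at a split with a missing feature value
#' (or an unseen level) the record follows the node's largest child.
#'
#' @param tree A [fit_tree()] result.
#' @param newdata data.frame containing the tree's feature columns.
#' @return Character vector of predicted labels.
#' @export
predict_tree <- function(tree, newdata) {
  stopifnot(inherits(tree, "ghd_tree"))
  missing_cols <- setdiff(tree$features, names(newdata))
  if (length(missing_cols) > 0L) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- tree$root
    while (!node$leaf) {
      val <- as.character(newdata[[node$feature]][i])
      child <- if (!is.na(val) && val %in% names(node$children)) val else
        node$default_child
      node <- node$children[[child]]
    }
    node$majority
  }, character(1))
}

#' Prune the subtree contributing the most false positives
#'
#' Re-routes the labelled data through the tree, counts, for every subtree
#' below the root, the false positives its leaves produce (records predicted
#' `case` whose true label is `control`), and replaces the subtree with the
#' largest false-positive count by a control-labelled leaf. Ties prefer the
#' deepest such subtree (the smallest cut achieving the same false-positive
#' removal), then the first in pre-order. A tree that produces no false
#' positives is returned unchanged. Specificity on the supplied data can
#' only rise; sensitivity can only fall.
#'
#' @param tree A [fit_tree()] result.
#' @param x,y The labelled data used to count false positives.
#' @return A `ghd_tree`, pruned (attribute `pruned_path` records the cut) or
#'   identical to the input.
#' @export
prune_fp_branch <- function(tree, x, y) {
  stopifnot(inherits(tree, "ghd_tree"))
  y <- as.character(y)

  route <- function(node, idx, path) {
    # returns data.frame(path, depth, fp) for every non-root subtree
    out <- list()
    if (node$leaf) return(out)
    v <- x[[node$feature]][idx]
    for (lev in names(node$children)) {
      sub <- idx[which(v %in% lev)]
      if (lev == node$default_child) {
        sub <- sort(c(sub, idx[is.na(v) |
                                 !(as.character(v) %in%
                                     names(node$children))]))
      }
      child <- node$children[[lev]]
      cpath <- c(path, lev)
      pred <- if (length(sub) > 0L)
        predict_subtree(child, x, sub) else character(0)
      fp <- sum(pred == "case" & y[sub] == "control")
      out[[length(out) + 1L]] <- list(path = cpath, depth = length(cpath),
                                      fp = fp)
      out <- c(out, route(child, sub, cpath))
    }
    out
  }
  cand <- route(tree$root, seq_len(nrow(x)), character(0))
  if (length(cand) == 0L) return(tree)
  fps <- vapply(cand, `[[`, numeric(1), "fp")
  if (max(fps) == 0) return(tree)
  depths <- vapply(cand, `[[`, numeric(1), "depth")
  best <- which(fps == max(fps))
  best <- best[order(-depths[best])][1L]
  path <- cand[[best]]$path

  replace_at <- function(node, path) {
    if (length(path) == 0L) {
      return(list(leaf = TRUE, n = node$n, counts = node$counts,
                  majority = "control", pruned = TRUE))
    }
    node$children[[path[1L]]] <- replace_at(node$children[[path[1L]]],
                                            path[-1L])
    node
  }
  tree$root <- replace_at(tree$root, path)
  attr(tree, "pruned_path") <- path
  tree
}

predict_subtree <- function(node, x, idx) {
  if (length(idx) == 0L) return(character(0))
  out <- character(length(idx))
  walk <- function(node, pos) {
    if (node$leaf) { out[pos] <<- node$majority; return(invisible()) }
    v <- x[[node$feature]][idx[pos]]
    routed <- rep(node$default_child, length(pos))
    known <- !is.na(v) & as.character(v) %in% names(node$children)
    routed[known] <- as.character(v[known])
    for (lev in unique(routed)) walk(node$children[[lev]],
                                     pos[routed == lev])
  }
  walk(node, seq_along(idx))
  out
}

#' @export
print.ghd_tree <- function(x, ...) {
  cat("<ghd_tree> quality=", x$quality, ", min_records=", x$min_records,
      "\n", sep = "")
  show <- function(node, indent, branch) {
    pad <- strrep("  ", indent)
    cnt <- paste(x$classes, node$counts, sep = "=", collapse = ", ")
    if (node$leaf) {
      cat(pad, branch, "-> ", node$majority, " [", cnt, "]",
          if (isTRUE(node$pruned)) " (pruned)" else "", "\n", sep = "")
    } else {
      cat(pad, branch, "split on ", node$feature, " [", cnt, "]\n",
          sep = "")
      for (lev in names(node$children)) {
        show(node$children[[lev]], indent + 1L,
             paste0(node$feature, "=", lev, " "))
      }
    }
  }
  show(x$root, 0L, "")
  invisible(x)
}

#' Serialize a tree to JSON
#'
#' @param tree A `ghd_tree`.
#' @param path Optional file path; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "ghd_tree"))
  payload <- list(classes = tree$classes, features = tree$features,
                  quality = tree$quality, min_records = tree$min_records,
                  root = tree$root)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Stratified repeated cross-validation of the tree model
#'
#' Repeatedly holds out a stratified test fraction, fits the tree
#' (optionally with false-positive branch pruning) on the remainder, and
#' reports per-repeat sensitivity, specificity and accuracy together with
#' their dispersion.
#'
#' @param x,y Feature data.frame and label factor.
#' @param reps Number of random splits, default 20.
#' @param test_frac Held-out fraction, default 0.2.
#' @param prune Apply [prune_fp_branch()] on the training data, default
#'   FALSE.
#' @param seed Integer seed for the repeated stratified sampling.
#' @param ... Passed to [fit_tree()].
#' @return List with `per_rep` (data.frame) and `summary` (means and SDs).
#' @export
cv_tree <- function(x, y, reps = 20L, test_frac = 0.2, prune = FALSE,
                    seed = 1L, ...) {
  y <- factor(y)
  set.seed(seed)
  res <- lapply(seq_len(reps), function(r) {
    test <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, max(1L, round(test_frac * length(idx))))
    }))
    train <- setdiff(seq_along(y), test)
    fit <- fit_tree(x[train, , drop = FALSE], y[train], ...)
    if (prune) fit <- prune_fp_branch(fit, x[train, , drop = FALSE],
                                      y[train])
    pred <- predict_tree(fit, x[test, , drop = FALSE])
    truth <- as.character(y[test])
    tp <- sum(pred == "case" & truth == "case")
    fp <- sum(pred == "case" & truth == "control")
    fn <- sum(pred == "control" & truth == "case")
    tn <- sum(pred == "control" & truth == "control")
    data.frame(rep = r,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               accuracy = (tp + tn) / length(test))
  })
  per_rep <- do.call(rbind, res)
  summ <- data.frame(
    metric = c("sensitivity", "specificity", "accuracy"),
    mean = vapply(per_rep[, -1], mean, numeric(1), na.rm = TRUE),
    sd = vapply(per_rep[, -1], stats::sd, numeric(1), na.rm = TRUE),
    row.names = NULL)
  list(per_rep = per_rep, summary = summ)
}
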