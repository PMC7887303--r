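#' Assemble a pipeline configuration
#'
#' Defaults reproduce the published analysis settings: gain-ratio splits,
#' minimum two records per node, no error-based post-pruning (only the
#' false-positive branch cut), 100-tree ensemble for feature relevance,
#' Wilson confidence intervals at 95%, and a validation significance level
#' of 1e-5.
#'
#' @param cutoffs Era cut-off table, see [era_cutoffs()].
#' @param tree_quality `"gain_ratio"` or `"gini"`.
#' @param min_records Minimum records per tree node.
#' @param fp_prune Apply the false-positive branch cut after fitting.
#' @param n_trees,mtry Forest parameters (NULL mtry = `ceiling(sqrt(p))`).
#' @param conf_level Confidence level for all intervals.
#' @param alpha Significance level of the validation binomial test.
#' @param or_min,p_max Feature-selection thresholds on the association
#'   panel.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cutoffs = era_cutoffs(),
                            tree_quality = "gain_ratio",
                            min_records = 2L, fp_prune = TRUE,
                            n_trees = 100L, mtry = NULL,
                            conf_level = 0.95, alpha = 1e-5,
                            or_min = 5, p_max = 1e-4) {
  structure(list(cutoffs = cutoffs, tree_quality = tree_quality,
                 min_records = min_records, fp_prune = fp_prune,
                 n_trees = n_trees, mtry = mtry, conf_level = conf_level,
                 alpha = alpha, or_min = or_min, p_max = p_max),
            class = "pipeline_config")
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full derivation-and-validation pipeline
#'
#' Executes association panel -> feature selection -> gain-ratio tree
#' (with optional false-positive branch cut) -> ensemble feature relevance
#' -> rule application -> diagnostic evaluation on a cohort, and writes a
#' report bundle: `association.tsv`, `tree.json`, `importance.tsv`,
#' `decisions.csv`, `report.json` and `run_log.txt`. Every file embeds the
#' seed and the configuration hash, so identical inputs yield identical
#' bundles.
#'
#' @param cohort A cohort data.frame, or `NULL` to simulate from `spec`.
#' @param spec A [cohort_spec()] used when `cohort` is `NULL`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param seed Integer seed for simulation and the ensemble.
#' @return Invisible list with `cohort`, `association`, `selected`,
#'   `tree`, `pruned_tree`, `importance`, `rule`, `report`, `axes`,
#'   `config_hash`, `seed`.
#' @export
run_pipeline <- function(cohort = NULL, spec = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         seed = 1L) {
  if (is.null(cohort)) {
    if (is.null(spec)) stop("supply a cohort or a spec", call. = FALSE)
    cohort <- simulate_cohort(spec, seed = seed)
  }
  if (!all(cohort$ghd_status %in% c("case", "control"))) {
    cohort <- ascertain_cohort(cohort, config$cutoffs)
  }
  hash <- config_hash(config)

  assoc <- association_table(cohort, conf_level = config$conf_level)
  selected <- select_predictors(assoc, or_min = config$or_min,
                                p_max = config$p_max)
  fm <- feature_matrix(cohort, predictors = selected)
  tree <- fit_tree(fm$x, fm$y, min_records = config$min_records,
                   quality = config$tree_quality)
  pruned <- if (isTRUE(config$fp_prune)) {
    prune_fp_branch(tree, fm$x, fm$y)
  } else tree
  imp <- fit_forest(fm$x, fm$y, n_trees = config$n_trees,
                    mtry = config$mtry, seed = seed)
  rule_eval <- apply_rule_to_cohort(cohort)
  report <- diagnostic_report(rule_eval$confusion,
                              conf_level = config$conf_level)
  prior <- mean(cohort$ghd_status == "case")
  axes <- validation_axes(report, prior_p = prior, alpha = config$alpha)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("# seed: %d  config: %s", seed, hash)
    ok <- FALSE
    on.exit(if (!ok) unlink(file.path(out_dir,
                                      c("association.tsv", "tree.json",
                                        "importance.tsv", "decisions.csv",
                                        "report.json", "run_log.txt"))),
            add = TRUE)

    write_stamped_tsv <- function(df, path) {
      con <- file(path, "w")
      writeLines(stamp, con)
      utils::write.table(df, con, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      close(con)
    }
    write_stamped_tsv(assoc, file.path(out_dir, "association.tsv"))
    write_stamped_tsv(as.data.frame(imp),
                      file.path(out_dir, "importance.tsv"))
    con <- file(file.path(out_dir, "decisions.csv"), "w")
    writeLines(stamp, con)
    utils::write.csv(rule_eval$decisions, con, row.names = FALSE)
    close(con)
    tree_to_json(pruned, file.path(out_dir, "tree.json"))
    m <- report$matrix
    jsonlite::write_json(
      list(seed = seed, config_hash = hash,
           confusion = list(tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn),
           n_ineligible = rule_eval$n_ineligible,
           metrics = list(
             sensitivity = report$sensitivity,
             specificity = report$specificity,
             ppv = report$ppv, npv = report$npv,
             accuracy = report$accuracy,
             f_measure = report$f_measure$est,
             lr_positive = if (is.infinite(report$lr_positive))
               ">1,000" else report$lr_positive,
             nnt = report$nnt),
           validation_axes = axes),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeLines(c(stamp,
                 sprintf("cohort: n=%d cases=%d", nrow(cohort),
                         sum(cohort$ghd_status == "case")),
                 sprintf("selected predictors: %s",
                         paste(selected, collapse = ", ")),
                 sprintf("ineligible excluded: %d",
                         rule_eval$n_ineligible)),
               file.path(out_dir, "run_log.txt"))
    ok <- TRUE
  }
  invisible(list(cohort = cohort, association = assoc,
                 selected = selected, tree = tree, pruned_tree = pruned,
                 importance = imp, rule = rule_eval, report = report,
                 axes = axes, config_hash = hash, seed = seed))
}
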