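#' Pipeline configuration
#'
#' Collects inputs and thresholds for [run_pipeline()]. Inputs may be file
#' paths (TSV/GMT, read with the package readers) or in-memory objects of
#' the same shapes.
#'
#' @param counts Count matrix, or path to a counts TSV.
#' @param samples Sample metadata data.frame, or path to a metadata TSV.
#' @param targets Optional target table (or path); enables the enrichment
#'   stage.
#' @param gene_sets Optional [gene_set_collection()] (or GMT path).
#' @param precursor_mapping Optional precursor-to-mature mapping (named
#'   vector or two-column data.frame); when given, counts are merged to
#'   mature level first.
#' @param min_total Abundance filter threshold, default 200.
#' @param p_thresh,lfc_thresh DE-calling thresholds, defaults 0.01 and 2.
#' @param log_base,pseudocount Log-FPM convention for the risk score.
#' @param background_n Enrichment background size N, default 20000.
#' @param covariates Model covariates beyond group, default `"age"`.
#' @param standardize_covariates Standardize covariates? Default FALSE.
#' @param size_factors_on `"filtered"` (default) estimates size factors on
#'   the abundance-filtered matrix; `"all"` uses the full mature-level
#'   matrix.
#' @param roc_direction Orientation passed to [roc_curve()]; default
#'   `"auto"` with the chosen orientation reported.
#' @param seed Seed for any stochastic stage (bootstrap CIs).
#' @param out_dir Optional output directory; when set, results TSVs, a JSON
#'   summary and a run log are written there.
#' @param case,control Group labels.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, samples, targets = NULL, gene_sets = NULL,
                            precursor_mapping = NULL, min_total = 200,
                            p_thresh = 0.01, lfc_thresh = 2, log_base = 2,
                            pseudocount = 1, background_n = 20000,
                            covariates = "age", standardize_covariates = FALSE,
                            size_factors_on = c("filtered", "all"),
                            roc_direction = "auto", seed = 1,
                            out_dir = NULL, case = "DR", control = "NDR") {
  size_factors_on <- match.arg(size_factors_on)
  stopifnot(min_total >= 0, p_thresh >= 0, p_thresh <= 1, lfc_thresh >= 0,
            background_n > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full serum miRNA analysis pipeline
#'
#' Stages, in order: read inputs, merge precursor counts to mature level,
#' abundance filter, median-of-ratios size factors and log-FPM,
#' negative-binomial Wald differential expression adjusted for the
#' configured covariates, LFC-weighted polygenic risk score with ROC/AUC/
#' Youden evaluation on the DE panel, and hypergeometric target-gene
#' enrichment when a target table and gene sets are supplied. Every stage
#' logs its row counts and threshold decisions; any stage error aborts with
#' the stage name. If the DE panel is empty the risk-score and enrichment
#' stages are skipped with a notice.
#'
#' The risk-score AUC is evaluated on the same samples that supplied the LFC
#' weights; the summary marks it `in_sample = TRUE` because such reuse
#' inflates the estimate.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a summary list: counts at each stage, the DE table and
#'   panel, risk-score/ROC results, enrichment table, and the log lines.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  counts <- stage("read_counts", {
    if (is.character(config$counts)) read_count_matrix(config$counts) else {
      validate_count_matrix(config$counts); config$counts
    }
  })
  samples <- stage("read_metadata", {
    if (is.character(config$samples)) {
      read_sample_metadata(config$samples, case = config$case, control = config$control)
    } else config$samples
  })
  logmsg("input: ", nrow(counts), " features x ", ncol(counts), " samples")

  if (!is.null(config$precursor_mapping)) {
    counts <- stage("merge_mature", merge_mature_counts(counts, config$precursor_mapping))
    logmsg("merged to ", nrow(counts), " mature miRNAs")
  }

  n_before <- nrow(counts)
  filtered <- stage("abundance_filter", filter_low_abundance(counts, config$min_total))
  logmsg("abundance filter (total >= ", config$min_total, "): ",
         nrow(filtered), " of ", n_before, " features retained")

  sf <- stage("size_factors", {
    basis <- if (config$size_factors_on == "filtered") filtered else counts
    estimate_size_factors(basis)
  })
  lf <- stage("normalize", log_fpm(fpm(filtered, sf), pseudocount = config$pseudocount,
                                   base = config$log_base))
  logmsg("size factors on ", config$size_factors_on, " matrix; log base ",
         config$log_base, ", pseudocount ", config$pseudocount)

  de_tab <- stage("differential_expression",
                  nb_de(filtered, samples, sf = sf, covariates = config$covariates,
                        standardize = config$standardize_covariates,
                        p_thresh = config$p_thresh, lfc_thresh = config$lfc_thresh))
  panel_tab <- de_tab[de_tab$de, , drop = FALSE]
  logmsg("differential expression: ", sum(de_tab$converged), " features tested, ",
         nrow(panel_tab), " DE at p <= ", config$p_thresh,
         " and |LFC| >= ", config$lfc_thresh)

  summary <- list(
    n_features_input = n_before, n_features_tested = sum(de_tab$converged),
    n_retained = nrow(filtered), n_de = nrow(panel_tab),
    de_panel = panel_tab$mirna, de_table = de_tab, size_factors = sf,
    thresholds = list(min_total = config$min_total, p_thresh = config$p_thresh,
                      lfc_thresh = config$lfc_thresh),
    risk_score = NULL, roc = NULL, auc_ci = NULL, youden = NULL,
    enrichment = NULL, log = NULL
  )

  if (nrow(panel_tab) == 0L) {
    logmsg("risk-score stage skipped: empty DE panel")
  } else {
    rs <- stage("risk_score", {
      w <- stats::setNames(panel_tab$lfc, panel_tab$mirna)
      polygenic_score(lf, w)
    })
    idx <- match(names(rs$score), samples$sample)
    labels <- as.character(samples$group[idx])
    roc <- stage("roc", roc_curve(rs$score, labels, case = config$case,
                                  direction = config$roc_direction))
    ci <- stage("auc_ci", auc_confidence_interval(
      if (roc$direction == "case_low") -rs$score else rs$score,
      labels, case = config$case, seed = config$seed))
    yj <- youden_cutoff(roc)
    logmsg(sprintf("risk score: AUC = %.3f [%.3f, %.3f] (direction %s, in-sample), ",
                   roc$auc, ci$lower, ci$upper, roc$direction),
           sprintf("optimal cutoff %.3f (sens %.3f, spec %.3f)",
                   yj$cutoff, yj$sensitivity, yj$specificity))
    summary$risk_score <- rs
    summary$roc <- roc
    summary$auc_ci <- ci
    summary$youden <- yj
    summary$in_sample <- TRUE
  }

  if (!is.null(config$targets) && nrow(panel_tab) > 0L) {
    targets <- stage("read_targets", {
      if (is.character(config$targets)) read_target_table(config$targets) else config$targets
    })
    gs <- stage("read_gene_sets", {
      if (is.character(config$gene_sets)) read_gmt(config$gene_sets) else config$gene_sets
    })
    enr <- stage("enrichment", {
      query <- collect_target_genes(panel_tab$mirna, targets)
      enrich_gene_sets(query, gs, N = config$background_n)
    })
    logmsg("enrichment: ", nrow(enr), " sets tested, top set '", enr$set[1L],
           "' raw p = ", format(enr$pvalue[1L], digits = 3))
    summary$enrichment <- enr
  } else if (!is.null(config$targets)) {
    logmsg("enrichment stage skipped: empty DE panel")
  }

  summary$log <- log_lines
  if (!is.null(config$out_dir)) write_pipeline_outputs(summary, config)
  invisible(summary)
}

#' @noRd
write_pipeline_outputs <- function(summary, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  utils::write.table(summary$de_table, out("de_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(summary$size_factors),
               size_factor = summary$size_factors),
    out("size_factors.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary$risk_score)) {
    utils::write.table(
      data.frame(sample = names(summary$risk_score$score),
                 score = summary$risk_score$score),
      out("risk_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary$roc$points, out("roc_points.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(summary$enrichment)) {
    utils::write.table(summary$enrichment, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  js <- list(
    n_features_input = summary$n_features_input,
    n_retained = summary$n_retained,
    n_features_tested = summary$n_features_tested,
    n_de = summary$n_de, de_panel = as.list(summary$de_panel),
    thresholds = summary$thresholds
  )
  if (!is.null(summary$roc)) {
    js$auc <- summary$roc$auc
    js$auc_ci <- c(summary$auc_ci$lower, summary$auc_ci$upper)
    js$direction <- summary$roc$direction
    js$in_sample <- TRUE
    js$youden <- summary$youden
  }
  if (!is.null(summary$enrichment)) {
    top <- summary$enrichment[1L, ]
    js$top_set <- top$set
    js$top_set_pvalue <- top$pvalue
    js$top_set_bonferroni <- top$bonferroni
  }
  jsonlite::write_json(js, out("summary.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(summary$log, out("run.log"))
  invisible(config$out_dir)
}
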