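#' Build a validated pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline into one serialisable
#' list; a run is reproducible from the configuration plus the input files
#' alone.
#'
#' @param expression path to the expression TSV (see [read_expression()]).
#' @param annotation path to the annotation TSV (optional when
#'   `risk_mode = "none"` and no survival stage is requested).
#' @param mapping optional probeset-to-symbol map path.
#' @param out_dir output directory (created if absent).
#' @param risk_mode `"survival_cutoff"`, `"subtype"`, or `"none"` (labels
#'   already present in the annotation `risk_label` column).
#' @param cutoff_days survival cutoff for risk labelling (default 730).
#' @param alpha DEG selection threshold (default 0.05).
#' @param grid penalty grid (default `seq(0, 1, 0.1)`).
#' @param k number of hubs (default 20).
#' @param orphan_policy,overlap see [merge_remaining()].
#' @param collapse_summary see [collapse_probesets()].
#' @param do_cluster run clustering + log-rank per best module.
#' @param do_resample run [resample_evaluate()] per best module.
#' @param reps re-sampling iterations (default 100).
#' @param n_features SVM-RFE signature size (default 30).
#' @param seed master seed; all stages derive their streams from it.
#' @return a `"pipeline_config"` list.
#' @export
pipeline_config <- function(expression, annotation = NULL, mapping = NULL,
                            out_dir = "modnet_run",
                            risk_mode = c("survival_cutoff", "subtype", "none"),
                            cutoff_days = 730L, alpha = 0.05,
                            grid = seq(0, 1, by = 0.1), k = 20L,
                            orphan_policy = "merge", overlap = "cardinality",
                            collapse_summary = "mean",
                            do_cluster = FALSE, do_resample = FALSE,
                            reps = 100L, n_features = 30L, seed = 1L) {
  risk_mode <- match.arg(risk_mode)
  cfg <- list(expression = expression, annotation = annotation,
              mapping = mapping, out_dir = out_dir, risk_mode = risk_mode,
              cutoff_days = cutoff_days, alpha = alpha, grid = grid, k = k,
              orphan_policy = orphan_policy, overlap = overlap,
              collapse_summary = collapse_summary, do_cluster = do_cluster,
              do_resample = do_resample, reps = reps,
              n_features = n_features, seed = seed)
  if (!file.exists(expression)) stop("expression file not found: ", expression)
  needs_ann <- risk_mode != "none" || do_cluster || do_resample
  if (needs_ann && is.null(annotation))
    stop("annotation file required for risk labelling / survival stages")
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes, in order: probeset collapsing (if a mapping is given), risk
#' labelling, the DEG t-test filter, the penalty scan, network export, the
#' adaptive module partition, and optionally per-module clustering/log-rank
#' and re-sampling classification.  All artifacts are written under
#' `config$out_dir` together with a machine-readable `manifest.json`
#' recording the configuration, its fingerprint, the seed and every stage
#' output.
#'
#' @param config a `"pipeline_config"` from [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stages <- list()

  mat <- run_stage("read_expression", read_expression(config$expression))
  if (!is.null(config$mapping)) {
    mat <- run_stage("collapse_probesets",
      collapse_probesets(mat, read_mapping(config$mapping),
                         summary = config$collapse_summary))
  }

  ann <- NULL
  if (!is.null(config$annotation)) {
    ann <- run_stage("read_annotation", read_annotation(config$annotation))
    if (config$risk_mode != "none") {
      ann <- run_stage("assign_risk",
        assign_risk(ann, config$risk_mode, cutoff_days = config$cutoff_days))
    } else if (!"risk_label" %in% colnames(ann)) {
      stop("stage 'assign_risk' failed: risk_mode = 'none' requires a ",
           "risk_label column in the annotation", call. = FALSE)
    }
    write_annotation(ann, out("annotation_labeled.tsv"))
    stages$risk_labels <- "annotation_labeled.tsv"
    mat <- mat[, intersect(colnames(mat), ann$sample_id), drop = FALSE]
    ann <- ann[match(colnames(mat), ann$sample_id), , drop = FALSE]
    # uninformative (excluded) samples are flagged in the written annotation
    # but removed from all downstream stages
    keep <- ann$risk_label != "excluded"
    mat <- mat[, keep, drop = FALSE]
    ann <- ann[keep, , drop = FALSE]
  }

  degs <- NULL
  dat <- mat
  if (!is.null(ann)) {
    labels <- ann$risk_label
    degs <- run_stage("deg_filter",
      ttest_degs(mat, labels, alpha = config$alpha))
    write_degs(degs, out("degs.tsv"), out("deg_genes.txt"))
    stages$degs <- "degs.tsv"
    sel <- degs$gene_id[degs$selected]
    if (length(sel) < config$k + 1L)
      stop("stage 'deg_filter' failed: only ", length(sel),
           " DEGs at alpha = ", config$alpha,
           "; too few to build a network over k = ", config$k, " hubs",
           call. = FALSE)
    dat <- mat[sel, , drop = FALSE]
  }

  scan <- run_stage("penalty_scan",
    penalty_scan(dat, grid = config$grid, k = config$k))
  write_scan(scan, out("penalty_scan.tsv"))
  stages$penalty_scan <- "penalty_scan.tsv"

  net <- scan$network
  run_stage("network_export",
    write_network(net, out("edges.tsv"), out("network.graphml"),
                  out("degree.tsv")))
  stages$network <- "edges.tsv"

  part <- run_stage("partition",
    partition_network(net, k = config$k,
                      orphan_policy = config$orphan_policy,
                      overlap = config$overlap))
  best <- part$best[[1L]]
  write_gmt(best, out("modules.gmt"))
  utils::write.table(part$e_table, out("e_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(best$merge_log, out("merge_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stages$partition <- "modules.gmt"

  if (isTRUE(config$do_cluster)) {
    if (is.null(ann))
      stop("stage 'cluster_survival' failed: annotation required",
           call. = FALSE)
    cs_rows <- lapply(seq_along(best$modules), function(i) {
      genes <- intersect(best$modules[[i]], rownames(mat))
      cs <- cluster_two_groups(mat[genes, , drop = FALSE], ann)
      data.frame(module = paste0("module_", i), n_genes = length(genes),
                 logrank_chisq = cs$logrank$statistic,
                 logrank_p = cs$logrank$p_value)
    })
    cs_tab <- do.call(rbind, cs_rows)
    utils::write.table(cs_tab, out("cluster_survival.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stages$cluster_survival <- "cluster_survival.tsv"
  }

  if (isTRUE(config$do_resample)) {
    if (is.null(ann))
      stop("stage 'resample_evaluate' failed: annotation required",
           call. = FALSE)
    for (i in seq_along(best$modules)) {
      genes <- intersect(best$modules[[i]], rownames(mat))
      rep_i <- run_stage("resample_evaluate",
        resample_evaluate(mat[genes, , drop = FALSE], ann$risk_label,
                          reps = config$reps,
                          n_features = config$n_features,
                          seed = split_seed(config$seed, 1000L + i)))
      write_resampling_report(rep_i,
                              out(sprintf("resampling_module_%d.json", i)),
                              out(sprintf("resampling_module_%d.tsv", i)),
                              out(sprintf("signatures_module_%d.gmt", i)))
      stages[[sprintf("resampling_module_%d", i)]] <-
        sprintf("resampling_module_%d.json", i)
    }
  }

  manifest <- list(
    package = "modnet",
    version = as.character(utils::packageVersion("modnet")),
    seed = config$seed,
    config = unclass(config),
    config_fingerprint = config_fingerprint(unclass(config)),
    selected_rho = scan$selected_rho,
    n_genes = nrow(dat), n_samples = ncol(dat),
    n_edges = nrow(net$edges),
    n_modules = length(best$modules),
    avg_overlap = best$avg_overlap,
    stages = stages)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
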