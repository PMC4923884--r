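#' Confusion matrix constructor
#'
#' @param TP,TN,FP,FN nonnegative integer counts.
#' @return an object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion-matrix counts must be nonnegative integers")
  if (sum(counts) == 0) stop("all-zero confusion matrix")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Binary classification metrics from a confusion matrix
#'
#' Sensitivity `SEN = TP/(TP+FN)`, specificity `SPC = TN/(TN+FP)`, accuracy
#' `ACC = (TP+TN)/(TP+TN+FP+FN)` and Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.  A metric
#' whose denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param cm a `"confusion_matrix"` (see [confusion_matrix()]).
#' @return named list with `SEN`, `SPC`, `ACC`, `MCC`.
#' @export
#' @examples
#' classification_metrics(confusion_matrix(TP = 13, TN = 192, FP = 19, FN = 13))
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spc <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + tn + fp + fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else NA_real_
  list(SEN = sen, SPC = spc, ACC = acc, MCC = mcc)
}

#' Two-group hierarchical clustering of samples on module genes
#'
#' Clusters the samples of an expression matrix (typically restricted to
#' one module's genes) by agglomerative hierarchical clustering and cuts the
#' tree at two groups.  The default distance is correlation distance
#' (`1 - Pearson correlation` between sample profiles) with Ward linkage:
#' correlation distance is the standard choice for expression clustering,
#' and Ward linkage recovers a two-class structure even when one class is
#' internally diffuse (near-zero pairwise correlations), where average
#' linkage degenerates.  When
#' survival annotation is supplied, the cluster with the smaller median
#' survival among samples with observed events is labelled high risk and a
#' log-rank comparison of the two clusters is attached.
#'
#' @param mat numeric matrix, genes x samples (>= 2 genes, >= 4 samples).
#' @param ann optional annotation data.frame with `sample_id`,
#'   `survival_days`, `event` covering the samples.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage any `hclust` method; default `"ward.D2"` (Ward on
#'   correlation distance); `"average"` and friends are accepted.
#' @return an object of class `"cluster_survival"`: list with `cluster`
#'   (named 1/2 vector over samples), `high_risk_cluster`, `risk`
#'   (named "high"/"low" per sample) and, when `ann` is given, `logrank`
#'   (list `statistic`, `p_value`).
#' @export
cluster_two_groups <- function(mat, ann = NULL,
                               distance = c("correlation", "euclidean"),
                               linkage = "ward.D2") {
  distance <- match.arg(distance)
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 4L) stop("need at least 4 samples")
  if (nrow(mat) < 2L) stop("need at least 2 genes")
  if (all(mat == mat[1L])) stop("constant expression matrix: no structure to cluster")
  d <- if (distance == "correlation") {
    sds <- apply(mat, 2L, stats::sd)
    if (any(sds == 0))
      stop("constant sample profile(s): correlation distance undefined for ",
           paste(head(colnames(mat)[sds == 0], 5L), collapse = ", "))
    stats::as.dist(1 - stats::cor(mat))
  } else {
    stats::dist(t(mat))
  }
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = 2L)
  names(cl) <- colnames(mat)
  res <- list(cluster = cl, high_risk_cluster = NA_integer_,
              risk = NULL, logrank = NULL)
  if (!is.null(ann)) {
    ann <- ann[match(names(cl), ann$sample_id), , drop = FALSE]
    if (any(is.na(ann$sample_id)))
      stop("annotation missing for clustered samples")
    med <- vapply(1:2, function(k) {
      ev <- ann$event & cl == k
      if (any(ev)) stats::median(ann$survival_days[ev])
      else stats::median(ann$survival_days[cl == k])
    }, 0)
    hi <- which.min(med)
    res$high_risk_cluster <- hi
    res$risk <- setNames(ifelse(cl == hi, "high", "low"), names(cl))
    res$logrank <- logrank(cl, ann)
  }
  structure(res, class = "cluster_survival")
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square comparison of the survival curves of two
#' groups, on one degree of freedom.
#'
#' @param groups vector of group labels per sample (exactly two distinct
#'   values), aligned with `ann` rows or named by sample id.
#' @param ann annotation data.frame with `sample_id`, `survival_days`,
#'   `event`.
#' @return list with `statistic` (chi-square) and `p_value`.
#' @export
logrank <- function(groups, ann) {
  if (!is.null(names(groups)))
    ann <- ann[match(names(groups), ann$sample_id), , drop = FALSE]
  if (length(groups) != nrow(ann))
    stop("groups and annotation do not align")
  g <- as.factor(groups)
  if (nlevels(g) < 2L) stop("log-rank needs two nonempty groups")
  if (nlevels(g) > 2L) stop("more than two groups")
  fit <- survival::survdiff(
    survival::Surv(ann$survival_days, as.integer(ann$event)) ~ g)
  stat <- fit$chisq
  list(statistic = unname(stat),
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Monte-Carlo random gene-set null for module survival separation
#'
#' Repeatedly samples random gene sets of the module's size from the network
#' genes, reruns the two-group clustering + log-rank analysis on each, and
#' summarises the resulting p-value distribution.  This asks whether the
#' module's survival separation could have arisen from an arbitrary same-size
#' gene set.
#'
#' @param mat numeric matrix, genes x samples (full expression matrix).
#' @param ann annotation data.frame (see [logrank()]).
#' @param network_genes character vector of genes eligible for sampling.
#' @param m gene-set size (typically the module size).
#' @param reps number of random sets (default 100).
#' @param seed RNG seed.
#' @param module_genes optional: the observed module; when given, its
#'   log-rank p is computed and compared against the null draws.
#' @param ... passed to [cluster_two_groups()].
#' @return list with `p_values` (length `reps`), `mean_p`, and when
#'   `module_genes` was given, `observed_p` and `frac_below` (fraction of
#'   null p-values below the observed one).
#' @export
random_geneset_null <- function(mat, ann, network_genes, m, reps = 100L,
                                seed = 1L, module_genes = NULL, ...) {
  network_genes <- intersect(network_genes, rownames(mat))
  if (m > length(network_genes))
    stop("m = ", m, " exceeds the ", length(network_genes),
         " available network genes")
  set.seed(seed)
  pvals <- vapply(seq_len(reps), function(i) {
    gs <- sample(network_genes, m)
    cs <- cluster_two_groups(mat[gs, , drop = FALSE], ann, ...)
    cs$logrank$p_value
  }, 0)
  out <- list(p_values = pvals, mean_p = mean(pvals))
  if (!is.null(module_genes)) {
    cs <- cluster_two_groups(mat[module_genes, , drop = FALSE], ann, ...)
    out$observed_p <- cs$logrank$p_value
    out$frac_below <- mean(pvals < out$observed_p)
  }
  out
}
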