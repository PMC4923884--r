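#' Select differentially expressed genes by per-gene t-test
#'
#' Classical two-sided Student's t-test (pooled variance by default) between
#' the high- and low-risk sample groups, one test per gene.  A gene is
#' selected when `p < alpha`; no multiple-testing correction is applied, by
#' design — the filter's purpose is to shortlist genes for network
#' estimation, not to control an error rate.
#'
#' Samples labelled `"excluded"` are removed before testing.  A gene with
#' zero variance in both groups is degenerate: it is reported with `p = 1`
#' (never selected) when the group means coincide, and `p = 0` when the
#' means differ exactly (the difference is then certain); either way it is
#' flagged in the `degenerate` column.
#'
#' @param mat numeric matrix, genes x samples.
#' @param labels character vector of risk labels aligned with `colnames(mat)`
#'   (values in `{"high","low","excluded"}`), or a factor/character vector
#'   with exactly two used levels.
#' @param alpha selection threshold on the p-value (strict `<`); default 0.05.
#' @param var_equal pooled-variance Student test when `TRUE` (default);
#'   Welch's unequal-variance test when `FALSE`.
#' @return a data.frame with one row per gene: `gene_id`, `t_statistic`,
#'   `p_value`, `selected`, `degenerate`.
#' @export
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' colnames(m) <- paste0("s", 1:6)
#' ttest_degs(m, c("high", "high", "high", "low", "low", "low"))
ttest_degs <- function(mat, labels, alpha = 0.05, var_equal = TRUE) {
  stopifnot(is.matrix(mat), length(labels) == ncol(mat))
  labels <- as.character(labels)
  keep <- labels != "excluded" & !is.na(labels)
  mat <- mat[, keep, drop = FALSE]
  labels <- labels[keep]
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop("need exactly two groups, got: ", paste(lev, collapse = ", "))
  g1 <- labels == lev[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (got ", n1, " and ", n2, ")")
  x1 <- mat[, g1, drop = FALSE]
  x2 <- mat[, !g1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, nrow(mat))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- (m1 - m2) / se
  degenerate <- se == 0
  tstat[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 0,
                              sign(m1[degenerate] - m2[degenerate]) * Inf)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  data.frame(gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             t_statistic = unname(tstat), p_value = unname(p),
             selected = unname(p < alpha), degenerate = unname(degenerate),
             stringsAsFactors = FALSE)
}

#' Write a DEG table and the selected-gene list
#'
#' @param degs result of [ttest_degs()].
#' @param path output TSV path for the full table.
#' @param genes_path optional path for a one-symbol-per-line list of the
#'   selected genes.
#' @return `path`, invisibly.
#' @export
write_degs <- function(degs, path, genes_path = NULL) {
  utils::write.table(degs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(genes_path))
    writeLines(degs$gene_id[degs$selected], genes_path)
  invisible(path)
}
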