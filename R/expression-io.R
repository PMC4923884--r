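#' Read a gene-expression matrix from delimited text
#'
#' Expects genes in rows and samples in columns: the first column holds gene
#' or probeset identifiers and the header row holds sample identifiers.
#' Duplicate gene/probeset identifiers are permitted at this stage (they are
#' resolved by [collapse_probesets()]); duplicate sample identifiers are an
#' error, as are non-numeric or non-finite cells.
#'
#' @param path path to a TSV or CSV file.
#' @param fmt `"tsv"` (default) or `"csv"`.
#' @return a numeric matrix (genes x samples) with `rownames` = gene ids and
#'   `colnames` = sample ids.
#' @seealso [write_expression()], [collapse_probesets()]
#' @export
read_expression <- function(path, fmt = c("tsv", "csv")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- if (fmt == "tsv") "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed header in ", path,
                          ": need an id column plus at least one sample")
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  gene_ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("non-numeric cell at row '", gene_ids[bad[1L]],
             "', column '", sample_ids[j], "'")
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(gene_ids, sample_ids)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop("non-finite value at row '", gene_ids[bad[1L]],
         "', column '", sample_ids[bad[2L]], "'")
  }
  m
}

#' Write a gene-expression matrix to delimited text
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample.
#'
#' @param mat numeric matrix, genes x samples, with dimnames.
#' @param path output path.
#' @param fmt `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, fmt = c("tsv", "csv")) {
  fmt <- match.arg(fmt)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  sep <- if (fmt == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample clinical annotation
#'
#' Annotation is a TSV with columns `sample_id`, `survival_days`, `event`
#' (0/1, 1 = death observed) and optionally `subtype`.
#'
#' @param path path to the annotation TSV.
#' @return a data.frame with one row per sample.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("annotation must contain a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample ids in annotation")
  if ("event" %in% colnames(df)) df$event <- as.logical(df$event)
  df
}

#' Write per-sample annotation
#' @param ann annotation data.frame (see [read_annotation()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  out <- ann
  if ("event" %in% colnames(out)) out$event <- as.integer(out$event)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probeset-to-gene-symbol map
#'
#' Two-column TSV (`probeset_id`, `gene_symbol`), no header required; a
#' header line naming the two columns is tolerated.
#'
#' @param path path to the mapping TSV.
#' @return a data.frame with columns `probeset_id`, `gene_symbol`.
#' @export
read_mapping <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("mapping file needs two columns")
  df <- df[, 1:2]
  colnames(df) <- c("probeset_id", "gene_symbol")
  if (identical(tolower(df[1L, 1L]), "probeset_id")) df <- df[-1L, ]
  df
}

#' Collapse probesets to gene symbols
#'
#' When several probesets map to the same gene symbol, only one is kept as
#' that gene's expression profile: the probeset whose per-probeset summary
#' statistic (mean across samples by default) is maximal.  Ties are broken by
#' the lexicographically smallest probeset id.  Probesets without a mapping
#' entry are dropped.
#'
#' @param mat numeric matrix, probesets x samples.
#' @param mapping data.frame with columns `probeset_id`, `gene_symbol`
#'   (see [read_mapping()]).
#' @param summary which per-probeset scalar decides "maximum value":
#'   `"mean"` (default), `"max"` (single largest value) or `"median"`.
#' @return a numeric matrix, genes x samples, one row per gene symbol,
#'   rownames = gene symbols.
#' @export
collapse_probesets <- function(mat, mapping,
                               summary = c("mean", "max", "median")) {
  summary <- match.arg(summary)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (is.null(mapping) || nrow(mapping) == 0L)
    stop("empty probeset-to-gene mapping")
  if (anyDuplicated(mapping$probeset_id))
    stop("a probeset maps to more than one gene symbol: ",
         paste(unique(mapping$probeset_id[duplicated(mapping$probeset_id)]),
               collapse = ", "))
  sym <- setNames(as.character(mapping$gene_symbol),
                  as.character(mapping$probeset_id))
  # rows already carrying a target gene symbol are self-mapped, which makes
  # collapsing idempotent
  selfmapped <- setdiff(unique(as.character(mapping$gene_symbol)), names(sym))
  if (length(selfmapped)) sym[selfmapped] <- selfmapped
  keep <- rownames(mat) %in% names(sym)
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0L) stop("no probeset in the matrix is covered by the mapping")
  gene <- unname(sym[rownames(mat)])
  score <- switch(summary,
    mean   = rowMeans(mat),
    max    = apply(mat, 1L, max),
    median = apply(mat, 1L, stats::median))
  ord <- order(gene, -score, rownames(mat), method = "radix")
  first <- !duplicated(gene[ord])
  sel <- ord[first]
  out <- mat[sel, , drop = FALSE]
  rownames(out) <- gene[sel]
  out[order(rownames(out)), , drop = FALSE]
}

#' Assign high/low risk labels from survival or subtype
#'
#' In `survival_cutoff` mode a sample with survival strictly longer than
#' `cutoff_days` is low risk; a sample that died within the cutoff is high
#' risk; a sample still alive with follow-up shorter than the cutoff is
#' uninformative and flagged `excluded` (retained, never dropped).  In
#' `subtype` mode samples whose `subtype` equals `low_risk_subtype` are low
#' risk and all others high risk.
#'
#' @param ann annotation data.frame with `sample_id` and, depending on mode,
#'   `survival_days` + `event` or `subtype`.
#' @param mode `"survival_cutoff"` or `"subtype"`.
#' @param cutoff_days integer cutoff; 365 = one year, 730 = two years.
#' @param low_risk_subtype subtype string labelled low risk in subtype mode.
#' @return `ann` with a `risk_label` column in `{"high","low","excluded"}`.
#' @export
#' @examples
#' ann <- data.frame(sample_id = c("s1", "s2"),
#'                   survival_days = c(400L, 200L), event = c(TRUE, FALSE))
#' assign_risk(ann, "survival_cutoff", 365)$risk_label
assign_risk <- function(ann, mode = c("survival_cutoff", "subtype"),
                        cutoff_days = 365L, low_risk_subtype = "PN") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(ann), "sample_id" %in% colnames(ann))
  if (mode == "survival_cutoff") {
    need <- c("survival_days", "event")
    miss <- setdiff(need, colnames(ann))
    if (length(miss))
      stop("survival mode requires columns: ", paste(miss, collapse = ", "))
    bad <- ann$sample_id[is.na(ann$survival_days) | is.na(ann$event)]
    if (length(bad))
      stop("missing survival_days/event for samples: ",
           paste(bad, collapse = ", "))
    if (any(ann$survival_days < 0)) stop("negative survival_days")
    lab <- ifelse(ann$survival_days > cutoff_days, "low",
           ifelse(ann$event, "high",
           ifelse(ann$survival_days < cutoff_days, "excluded", "high")))
  } else {
    if (!"subtype" %in% colnames(ann))
      stop("subtype mode requires a 'subtype' column")
    bad <- ann$sample_id[is.na(ann$subtype)]
    if (length(bad))
      stop("missing subtype for samples: ", paste(bad, collapse = ", "))
    lab <- ifelse(ann$subtype == low_risk_subtype, "low", "high")
  }
  ann$risk_label <- lab
  ann
}
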