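#' Gene network from the support of a precision estimate
#'
#' Draws an undirected edge between genes i and j whenever the off-diagonal
#' precision entry exceeds `support_tol` in absolute value in either triangle
#' (symmetrised by OR).  Self-loops are never created.
#'
#' @param est a `"precision_estimate"` from [graphical_lasso()], or a bare
#'   symmetric precision matrix.
#' @param support_tol strict threshold deciding "nonzero"; default `1e-8`.
#' @return an object of class `"gene_network"`: list with `nodes` (gene
#'   ids), `edges` (data.frame `gene_a`, `gene_b`, `weight` = theta_ij, with
#'   `gene_a < gene_b`), `degree` (named integer vector over all nodes) and
#'   `source` (the precision estimate, if one was supplied).
#' @export
network_from_precision <- function(est, support_tol = 1e-8) {
  if (inherits(est, "precision_estimate")) {
    if (!isTRUE(est$converged))
      stop("precision estimate is not converged; refusing to read a network ",
           "off it")
    theta <- est$theta
    src <- est
  } else {
    theta <- est
    src <- NULL
  }
  stopifnot(is.matrix(theta), nrow(theta) == ncol(theta))
  ids <- rownames(theta) %||% as.character(seq_len(nrow(theta)))
  sup <- abs(theta) > support_tol
  sup <- sup | t(sup)                       # OR-symmetrised
  diag(sup) <- FALSE
  idx <- which(sup & upper.tri(sup), arr.ind = TRUE)
  ord <- order(ids[idx[, 1L]], ids[idx[, 2L]], method = "radix")
  idx <- idx[ord, , drop = FALSE]
  edges <- data.frame(gene_a = ids[idx[, 1L]], gene_b = ids[idx[, 2L]],
                      weight = theta[idx], stringsAsFactors = FALSE)
  deg <- setNames(integer(length(ids)), ids)
  if (nrow(edges)) {
    tab <- table(c(edges$gene_a, edges$gene_b))
    deg[names(tab)] <- as.integer(tab)
  }
  structure(list(nodes = ids, edges = edges, degree = deg, source = src),
            class = "gene_network")
}

#' Build a gene network from an explicit edge list
#'
#' For precomputed networks (e.g. read back from an edge-list file).
#' Duplicate pairs and self-loops are rejected.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and optionally
#'   `weight`.
#' @param nodes optional character vector of node ids (to keep isolated
#'   nodes); defaults to the ids appearing in `edges`.
#' @return a `"gene_network"` object (see [network_from_precision()]).
#' @export
network_from_edges <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("gene_a", "gene_b") %in% colnames(edges)))
  a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
  if (any(a == b)) stop("self-loops are not allowed")
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) stop("duplicated edges in edge list")
  w <- if ("weight" %in% colnames(edges)) as.numeric(edges$weight) else rep(1, length(a))
  ord <- order(lo, hi, method = "radix")
  edges <- data.frame(gene_a = lo[ord], gene_b = hi[ord], weight = w[ord],
                      stringsAsFactors = FALSE)
  ids <- sort(unique(c(nodes, edges$gene_a, edges$gene_b)))
  deg <- setNames(integer(length(ids)), ids)
  tab <- table(c(edges$gene_a, edges$gene_b))
  deg[names(tab)] <- as.integer(tab)
  structure(list(nodes = ids, edges = edges, degree = deg, source = NULL),
            class = "gene_network")
}

#' @exportS3Method base::print
print.gene_network <- function(x, ...) {
  cat("Gene network:", length(x$nodes), "nodes,", nrow(x$edges), "edges;",
      sum(x$degree > 0), "nodes with degree >= 1\n")
  invisible(x)
}

#' Neighbours of a node
#' @param net a `"gene_network"`.
#' @param node a node id.
#' @return character vector of adjacent gene ids.
#' @export
neighbors_of <- function(net, node) {
  e <- net$edges
  sort(unique(c(e$gene_b[e$gene_a == node], e$gene_a[e$gene_b == node])))
}

#' Convert a gene network to an igraph object
#' @param net a `"gene_network"`.
#' @return an undirected `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  g
}

#' Write a network as edge-list TSV, GraphML and a degree table
#'
#' @param net a `"gene_network"`.
#' @param edges_path path for the edge-list TSV (`gene_a`, `gene_b`,
#'   `weight`).
#' @param graphml_path optional path for GraphML output.
#' @param degree_path optional path for a `gene`/`degree` TSV.
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(net, edges_path, graphml_path = NULL,
                          degree_path = NULL) {
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  if (!is.null(degree_path))
    utils::write.table(
      data.frame(gene = names(net$degree), degree = unname(net$degree)),
      degree_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges_path)
}

#' Read a network from an edge-list TSV
#' @param path TSV with columns `gene_a`, `gene_b` and optionally `weight`.
#' @return a `"gene_network"`.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  network_from_edges(df)
}

#' Power-law check of the degree distribution
#'
#' Scale-free networks show a straight line in log-frequency versus
#' log-degree.  This diagnostic fits that line by least squares over nodes
#' with degree >= 1 and reports the slope (the negated power-law exponent)
#' and R squared.  It is a shape check, not a formal power-law test.
#'
#' @param net a `"gene_network"` with at least 10 positive-degree nodes.
#' @return list with `slope`, `r_squared`, `n_degrees` (distinct degree
#'   values), `scale_free_like` (negative slope with R squared > 0.7) and
#'   `note` (degeneracy warnings).
#' @export
degree_distribution_fit <- function(net) {
  deg <- net$degree[net$degree >= 1L]
  if (length(deg) == 0L) stop("network has no edges")
  if (length(deg) < 10L)
    stop("need at least 10 nodes with degree >= 1 (got ", length(deg), ")")
  tab <- table(deg)
  d <- as.numeric(names(tab))
  f <- as.numeric(tab)
  note <- character()
  if (length(d) < 3L) {
    note <- c(note, "fewer than 3 distinct degrees; fit is degenerate")
    warning("degree distribution has fewer than 3 distinct values; ",
            "power-law fit is degenerate")
  }
  if (length(d) == 1L) {
    return(list(slope = 0, r_squared = NA_real_, n_degrees = 1L,
                scale_free_like = FALSE,
                note = c(note, "single degree value; not scale-free")))
  }
  fit <- stats::lm.fit(cbind(1, log(d)), log(f))
  slope <- unname(fit$coefficients[2L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log(f) - mean(log(f)))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (abs(slope) < 0.1)
    note <- c(note, "near-zero slope; not scale-free")
  list(slope = slope, r_squared = r2, n_degrees = length(d),
       scale_free_like = isTRUE(slope < 0 && !is.na(r2) && r2 > 0.7),
       note = note)
}
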