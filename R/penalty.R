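#' Scan the penalty grid and select the working penalty
#'
#' Fits the graphical lasso at every penalty on a fixed grid (0 to 1 in
#' steps of 0.1 by default), builds the network at each penalty, and records
#' the edge count and whether the network admits at least one seed module
#' set — the feasibility requirement of the partition algorithm.  The
#' selected penalty is the smallest feasible one, i.e. the value that keeps
#' the most edges while still permitting a partition (network sparsity grows
#' with the penalty, so smaller feasible penalties retain more edges).
#'
#' Genes are standardised to unit variance before covariance estimation by
#' default, making one penalty scale comparable across genes.  A zero
#' penalty requires an invertible covariance; when there are more genes than
#' samples that grid point is skipped with a warning.
#'
#' @param mat numeric matrix, genes x samples.
#' @param grid ascending nonnegative penalty values; default
#'   `seq(0, 1, 0.1)`.
#' @param k number of hubs used for the seed-set feasibility check.
#' @param support_tol edge threshold, see [network_from_precision()].
#' @param standardize scale genes to unit variance first (default `TRUE`).
#' @param ml covariance normalisation, see [empirical_covariance()].
#' @param ... further arguments passed to [graphical_lasso()].
#' @return an object of class `"penalty_scan"`: list with `selected_rho`,
#'   `table` (data.frame `rho`, `n_edges`, `n_nodes_degree_ge1`,
#'   `has_seed_set`, `converged`), `network` (the network at the selected
#'   penalty) and `edge_monotone` (`FALSE` + warning if the edge count ever
#'   increased along the grid).
#' @export
penalty_scan <- function(mat, grid = seq(0, 1, by = 0.1), k = 20L,
                         support_tol = 1e-8, standardize = TRUE,
                         ml = TRUE, ...) {
  if (length(grid) == 0L) stop("empty penalty grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be sorted ascending")
  if (any(grid < 0)) stop("penalties must be nonnegative")
  p <- nrow(mat); n <- ncol(mat)
  x <- mat
  if (standardize) {
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance gene(s) cannot be standardized: ",
           paste(head(rownames(x)[sds == 0], 5L), collapse = ", "))
    x <- (x - rowMeans(x)) / sds
  }
  s <- empirical_covariance(x, ml = ml)

  rows <- list()
  nets <- list()
  for (rho in grid) {
    if (rho == 0 && p > n) {
      warning("skipping rho = 0: empirical covariance is not invertible ",
              "when genes outnumber samples (P = ", p, " > N = ", n, ")")
      rows[[length(rows) + 1L]] <- data.frame(
        rho = 0, n_edges = NA_integer_, n_nodes_degree_ge1 = NA_integer_,
        has_seed_set = NA, converged = NA)
      next
    }
    est <- graphical_lasso(s, rho, ...)
    net <- network_from_precision(est, support_tol = support_tol)
    has_seed <- FALSE
    if (est$converged && sum(net$degree >= 1L) >= k) {
      mods <- initialize_modules(net, select_hubs(net, k))
      has_seed <- length(enumerate_seed_sets(mods)) > 0L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      rho = rho, n_edges = nrow(net$edges),
      n_nodes_degree_ge1 = sum(net$degree >= 1L),
      has_seed_set = has_seed, converged = est$converged)
    nets[[as.character(rho)]] <- net
  }
  tab <- do.call(rbind, rows)
  feasible <- which(!is.na(tab$has_seed_set) & tab$has_seed_set & tab$converged)
  if (length(feasible) == 0L)
    stop("no penalty on the grid yields a network with a seed module set; ",
         "try a finer grid (e.g. steps of 0.05) or fewer hubs")
  sel <- tab$rho[feasible[1L]]
  edge_monotone <- TRUE
  ne <- tab$n_edges[!is.na(tab$n_edges)]
  if (any(diff(ne) > 0)) {
    edge_monotone <- FALSE
    warning("edge count increased along the penalty grid; solver results ",
            "may be unreliable")
  }
  structure(list(selected_rho = sel, table = tab,
                 network = nets[[as.character(sel)]],
                 edge_monotone = edge_monotone),
            class = "penalty_scan")
}

#' @exportS3Method base::print
print.penalty_scan <- function(x, ...) {
  cat("Penalty scan: selected rho =", x$selected_rho, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a penalty-scan report as TSV
#' @param scan a `"penalty_scan"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
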