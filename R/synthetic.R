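#' Synthetic hub-structured Gaussian graphical model
#'
#' Builds a known sparse precision matrix with `n_hubs` star blocks (a hub
#' connected to `hub_degree` leaves) plus optional random background edges
#' between non-hub genes, with the diagonal loaded so the matrix is safely
#' positive definite.  Star members define the planted module truth.  The
#' star edge weight is `0.5 / sqrt(hub_degree)` by default: strong enough
#' that the implied marginal correlations clear a coarse penalty grid, while
#' keeping the smallest eigenvalue of the star block at `1 - 0.5 = 0.5`.
#'
#' @param p number of genes.
#' @param n_hubs number of hub/star blocks.
#' @param hub_degree leaves per hub; requires `n_hubs * (hub_degree + 1) <= p`.
#' @param background_edges random extra edges among non-hub genes (default
#'   10), capped so that no background node's degree reaches `hub_degree`
#'   (planted hubs keep the maximal degrees).
#' @param seed RNG seed.
#' @param star_weight off-diagonal precision weight of hub-leaf pairs.
#' @param min_eigen smallest eigenvalue guaranteed by diagonal loading
#'   (default 0.05).
#' @param effect_size per-gene mean shift between the two patient classes,
#'   in marginal-sd units, applied to the first module's genes by
#'   [sample_expression()] (default 0 = null model).
#' @return an object of class `"synthetic_model"`: list with
#'   `precision_true` (sparse `Matrix`), `module_truth` (named vector;
#'   module number or `NA` for background genes), `hub_truth`,
#'   `effect_size`, `shift_genes`, `survival_rates` (per-class exponential
#'   event rates per day) and `seed`.
#' @export
make_model <- function(p, n_hubs = 2L, hub_degree = 8L,
                       background_edges = 10L, seed = 1L,
                       star_weight = 0.5 / sqrt(hub_degree),
                       min_eigen = 0.05, effect_size = 0) {
  if (n_hubs * (hub_degree + 1L) > p)
    stop("infeasible sizes: n_hubs * (hub_degree + 1) = ",
         n_hubs * (hub_degree + 1L), " > p = ", p)
  genes <- sprintf("g%0*d", nchar(p), seq_len(p))
  set.seed(seed)
  ii <- integer(); jj <- integer(); ww <- numeric()
  module <- setNames(rep(NA_integer_, p), genes)
  hubs <- character(n_hubs)
  nxt <- 1L
  for (h in seq_len(n_hubs)) {
    hub <- nxt
    leaves <- seq(nxt + 1L, nxt + hub_degree)
    hubs[h] <- genes[hub]
    module[c(hub, leaves)] <- h
    ii <- c(ii, rep(hub, hub_degree)); jj <- c(jj, leaves)
    ww <- c(ww, rep(star_weight, hub_degree))
    nxt <- nxt + hub_degree + 1L
  }
  free <- which(is.na(module))
  if (background_edges > 0L && length(free) >= 2L) {
    deg <- setNames(integer(length(free)), free)
    added <- 0L; guard <- 0L
    while (added < background_edges && guard < 50L * background_edges) {
      guard <- guard + 1L
      pair <- sample(free, 2L)
      a <- min(pair); b <- max(pair)
      if (any(ii == a & jj == b)) next
      if (deg[as.character(a)] + 1L >= hub_degree ||
          deg[as.character(b)] + 1L >= hub_degree) next
      ii <- c(ii, a); jj <- c(jj, b); ww <- c(ww, star_weight)
      deg[as.character(a)] <- deg[as.character(a)] + 1L
      deg[as.character(b)] <- deg[as.character(b)] + 1L
      added <- added + 1L
    }
  }
  theta <- Matrix::sparseMatrix(i = c(ii, seq_len(p)), j = c(jj, seq_len(p)),
                                x = c(ww, rep(1, p)), dims = c(p, p),
                                symmetric = TRUE)
  dimnames(theta) <- list(genes, genes)
  # diagonal loading: exact eigenvalue for moderate p, Gershgorin bound
  # (cheap, conservative) for large p
  lam_min <- if (p <= 2000L) {
    min(eigen(as.matrix(theta), symmetric = TRUE, only.values = TRUE)$values)
  } else {
    min(Matrix::diag(theta) - (Matrix::rowSums(abs(theta)) - abs(Matrix::diag(theta))))
  }
  if (lam_min < min_eigen)
    Matrix::diag(theta) <- Matrix::diag(theta) + (min_eigen - lam_min)
  # survival: exponential event times per risk class; the high-risk rate puts
  # ~40% of events inside the 2-year cutoff, the low-risk rate ~15%
  rates <- c(high = -log(0.6) / 730, low = -log(0.85) / 730)
  structure(list(precision_true = theta, module_truth = module,
                 hub_truth = hubs, effect_size = effect_size,
                 shift_genes = genes[which(module == 1L)],
                 survival_rates = rates, seed = seed,
                 star_weight = star_weight),
            class = "synthetic_model")
}

#' True edge set of a synthetic model
#' @param model a `"synthetic_model"`.
#' @return data.frame `gene_a`, `gene_b` (sorted pairs) of the nonzero
#'   off-diagonal support of the true precision matrix.
#' @export
true_edges <- function(model) {
  th <- as(as(model$precision_true, "generalMatrix"), "TsparseMatrix")
  keep <- th@x != 0 & th@i < th@j
  i <- th@i[keep] + 1L
  j <- th@j[keep] + 1L
  ids <- rownames(model$precision_true)
  df <- data.frame(gene_a = pmin(ids[i], ids[j]),
                   gene_b = pmax(ids[i], ids[j]),
                   stringsAsFactors = FALSE)
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

#' Sample expression and survival annotation from a synthetic model
#'
#' Draws `n_per_class` samples per patient class from the multivariate
#' normal with covariance equal to the inverse of the true precision matrix
#' (via the precision Cholesky factor, so large sparse models stay cheap).
#' High-risk samples receive a mean shift of `effect_size` marginal standard
#' deviations on the model's shift genes.  Survival days are exponential
#' with class-dependent rates; censoring is uniform on [0, 3650] days.
#'
#' @param model a `"synthetic_model"` from [make_model()].
#' @param n_per_class samples per class (length 1 or 2: high, low).
#' @param seed RNG seed.
#' @return list with `expression` (genes x samples matrix) and `annotation`
#'   (data.frame `sample_id`, `survival_days`, `event`, `class`).
#' @export
sample_expression <- function(model, n_per_class = 100L, seed = 1L) {
  stopifnot(inherits(model, "synthetic_model"))
  n_per_class <- rep_len(n_per_class, 2L)
  n <- sum(n_per_class)
  theta <- model$precision_true
  p <- nrow(theta)
  genes <- rownames(theta)
  set.seed(seed)
  z <- matrix(stats::rnorm(p * n), p, n)
  r <- Matrix::chol(theta)                      # theta = R'R, upper triangular
  x <- as.matrix(Matrix::solve(r, z))           # cov(x) = theta^-1
  dimnames(x) <- list(genes, sprintf("s%0*d", nchar(n), seq_len(n)))
  cls <- rep(c("high", "low"), n_per_class)
  if (model$effect_size != 0 && length(model$shift_genes)) {
    marg_sd <- sqrt(Matrix::diag(Matrix::solve(theta)))
    names(marg_sd) <- genes
    sel <- model$shift_genes
    # alternate the shift direction across genes: modules mix up- and
    # down-regulated members, and a uniform offset would be invisible to
    # correlation-based sample clustering
    dir <- rep_len(c(1, -1), length(sel))
    x[sel, cls == "high"] <- x[sel, cls == "high"] +
      model$effect_size * dir * marg_sd[sel]
  }
  rate <- model$survival_rates[cls]
  t_event <- stats::rexp(n, rate = rate)
  t_cens <- stats::runif(n, 0, 3650)
  ann <- data.frame(sample_id = colnames(x),
                    survival_days = as.integer(round(pmin(t_event, t_cens))),
                    event = t_event <= t_cens,
                    class = cls,
                    stringsAsFactors = FALSE)
  list(expression = x, annotation = ann)
}

#' Write the module/hub truth table of a synthetic model
#' @param model a `"synthetic_model"`.
#' @param path output TSV path (`gene`, `module`, `is_hub`).
#' @return `path`, invisibly.
#' @export
write_truth <- function(model, path) {
  df <- data.frame(gene = names(model$module_truth),
                   module = unname(model$module_truth),
                   is_hub = names(model$module_truth) %in% model$hub_truth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
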