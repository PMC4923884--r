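# linear SVM weight vector |w| per feature (features = rows of mat)
svm_weights <- function(mat, labels, cost = 1) {
  fit <- e1071::svm(x = t(mat), y = as.factor(labels), kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)   # 1 x features
  abs(as.vector(w))
}

#' SVM-RFE gene selection
#'
#' Recursive feature elimination with a linear max-margin classifier: fit,
#' rank genes by the magnitude of their weight in the separating hyperplane,
#' drop the lowest-ranked fraction, refit on the survivors, and repeat until
#' `n_features` genes remain.  The weight magnitude of a gene measures its
#' contribution to the decision boundary, so repeatedly pruning the weakest
#' genes concentrates the signature.  Features are standardised internally
#' (training statistics only).
#'
#' @param mat numeric matrix, genes x samples (training data only).
#' @param labels two-class label vector aligned with columns.
#' @param n_features number of genes to keep (default 30).
#' @param step_frac fraction of remaining genes eliminated per round
#'   (default 0.1; at least one gene per round).  Use a small value such as
#'   `1e-9` for classic one-gene-per-round elimination.
#' @param cost SVM cost parameter used during ranking (default 1).
#' @return character vector of `n_features` gene ids, best-ranked first
#'   (final-model weight order; ties broken by gene id).
#' @export
svm_rfe_select <- function(mat, labels, n_features = 30L, step_frac = 0.1,
                           cost = 1) {
  stopifnot(is.matrix(mat), length(labels) == ncol(mat))
  if (length(unique(labels)) != 2L) stop("need exactly two classes")
  if (min(table(labels)) < 2L) stop("need >= 2 samples per class")
  if (n_features > nrow(mat))
    stop("n_features = ", n_features, " exceeds the ", nrow(mat),
         " available genes")
  x <- mat
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  x <- (x - mu) / sdv
  surviving <- rownames(x) %||% as.character(seq_len(nrow(x)))
  rownames(x) <- surviving
  while (length(surviving) > n_features) {
    w <- svm_weights(x[surviving, , drop = FALSE], labels, cost = cost)
    ord <- order(w, surviving, method = "radix")  # weakest first, id ties
    n_drop <- max(1L, floor(step_frac * length(surviving)))
    n_drop <- min(n_drop, length(surviving) - n_features)
    surviving <- surviving[-ord[seq_len(n_drop)]]
  }
  w <- svm_weights(x[surviving, , drop = FALSE], labels, cost = cost)
  surviving[order(-w, surviving, method = "radix")]
}

#' Default SVM hyperparameter grid
#'
#' Linear and RBF kernels over logarithmic cost/gamma ranges, searched by
#' cross-validation in [resample_evaluate()].
#'
#' @return data.frame with columns `kernel`, `cost`, `gamma`.
#' @export
default_svm_grid <- function() {
  cost <- 2^c(-5, -3, -1, 1, 3, 5, 7)
  gamma <- 2^c(-15, -11, -7, -3, 1)
  rbind(
    data.frame(kernel = "linear", cost = cost, gamma = NA_real_),
    expand.grid(kernel = "radial", cost = cost, gamma = gamma,
                stringsAsFactors = FALSE))
}

fit_svm <- function(x, y, kernel, cost, gamma) {
  if (kernel == "linear")
    e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE)
  else
    e1071::svm(x = x, y = y, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE)
}

# stratified k-fold assignment (deterministic given the RNG state)
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

grid_search_cv <- function(x, y, grid, folds = 5L) {
  fold <- stratified_folds(y, folds)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) return(0)
      fit <- fit_svm(x[tr, , drop = FALSE], y[tr],
                     grid$kernel[g], grid$cost[g], grid$gamma[g])
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, 0)
  grid[which.max(acc), , drop = FALSE]   # first best in grid order
}

#' Re-sampling evaluation of a module's predictive ability
#'
#' Repeated random re-sampling classification of the risk groups from one
#' module's expression profiles.  Each iteration: (1) balance the classes
#' 1:1 by subsampling the majority class, (2) split 4:1 into training and
#' validation, stratified by class, (3) select genes by SVM-RFE on the
#' training split only, (4) pick SVM hyperparameters by stratified 5-fold
#' cross-validated grid search on the training split, (5) fit and evaluate
#' on the held-out validation split.  Per-iteration confusion matrices and
#' SEN/SPC/ACC/MCC are reported along with their arithmetic means.
#'
#' All randomness is driven by per-iteration seeds derived from the single
#' `seed` argument via [split_seed()], so reports are exactly reproducible.
#'
#' @param mat numeric matrix, genes x samples, restricted to one module.
#' @param labels class labels per sample (two classes; `"excluded"` samples
#'   are removed first).  The positive class is `"high"` when present,
#'   otherwise the first sorted level.
#' @param reps number of re-sampling iterations (default 100).
#' @param train_frac training fraction of the 4:1 split (default 0.8).
#' @param n_features genes kept by SVM-RFE (default 30, clamped to the
#'   number of available genes with a message).
#' @param seed master seed.
#' @param grid hyperparameter grid (see [default_svm_grid()]).
#' @param cv_folds cross-validation folds for the grid search (default 5).
#' @param step_frac RFE elimination fraction per round, see
#'   [svm_rfe_select()].
#' @return an object of class `"resampling_report"`: list with
#'   `per_iteration` (data.frame `iteration`, `seed`, `TP`, `TN`, `FP`,
#'   `FN`, `SEN`, `SPC`, `ACC`, `MCC`), `selected_genes` (list of
#'   per-iteration signatures), `averages` (mean SEN/SPC/ACC/MCC) and the
#'   configuration used.
#' @export
resample_evaluate <- function(mat, labels, reps = 100L, train_frac = 0.8,
                              n_features = 30L, seed = 1L,
                              grid = default_svm_grid(), cv_folds = 5L,
                              step_frac = 0.1) {
  stopifnot(is.matrix(mat), length(labels) == ncol(mat))
  keep <- labels != "excluded" & !is.na(labels)
  mat <- mat[, keep, drop = FALSE]
  labels <- as.character(labels[keep])
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("need exactly two classes")
  pos <- if ("high" %in% lev) "high" else lev[1L]
  neg <- setdiff(lev, pos)
  if (min(table(labels)) < 5L)
    stop("each class needs >= 5 samples for the 4:1 split")
  if (n_features > nrow(mat)) {
    message("n_features reduced from ", n_features, " to ", nrow(mat),
            " (module size)")
    n_features <- nrow(mat)
  }

  rows <- vector("list", reps)
  gene_lists <- vector("list", reps)
  for (i in seq_len(reps)) {
    it_seed <- split_seed(seed, i)
    set.seed(it_seed)
    # 1:1 balance by subsampling the majority class
    idx_pos <- which(labels == pos)
    idx_neg <- which(labels == neg)
    nmin <- min(length(idx_pos), length(idx_neg))
    idx_pos <- sort(sample(idx_pos, nmin))
    idx_neg <- sort(sample(idx_neg, nmin))
    # stratified 4:1 split
    ntr <- floor(train_frac * nmin)
    if (ntr < 4L || nmin - ntr < 1L)
      stop("class too small for a ", train_frac, " training split")
    tr <- c(sample(idx_pos, ntr), sample(idx_neg, ntr))
    va <- setdiff(c(idx_pos, idx_neg), tr)
    xtr <- mat[, tr, drop = FALSE]
    ytr <- factor(labels[tr], levels = c(neg, pos))
    # feature standardisation from training statistics only
    mu <- rowMeans(xtr)
    sdv <- apply(xtr, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    genes <- svm_rfe_select(xtr, ytr, n_features = n_features,
                            step_frac = step_frac)
    gene_lists[[i]] <- genes
    ztr <- t((xtr[genes, , drop = FALSE] - mu[genes]) / sdv[genes])
    zva <- t((mat[genes, va, drop = FALSE] - mu[genes]) / sdv[genes])
    best <- grid_search_cv(ztr, ytr, grid, folds = cv_folds)
    fit <- fit_svm(ztr, ytr, best$kernel, best$cost, best$gamma)
    pred <- stats::predict(fit, zva)
    truth <- factor(labels[va], levels = c(neg, pos))
    cm <- confusion_matrix(TP = sum(pred == pos & truth == pos),
                           TN = sum(pred == neg & truth == neg),
                           FP = sum(pred == pos & truth == neg),
                           FN = sum(pred == neg & truth == pos))
    met <- classification_metrics(cm)
    rows[[i]] <- data.frame(iteration = i, seed = it_seed,
                            TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN,
                            SEN = met$SEN, SPC = met$SPC, ACC = met$ACC,
                            MCC = met$MCC)
  }
  per <- do.call(rbind, rows)
  averages <- colMeans(per[, c("SEN", "SPC", "ACC", "MCC")], na.rm = TRUE)
  structure(list(per_iteration = per, selected_genes = gene_lists,
                 averages = as.list(averages),
                 config = list(reps = reps, train_frac = train_frac,
                               n_features = n_features, seed = seed,
                               cv_folds = cv_folds, step_frac = step_frac,
                               positive_class = pos)),
            class = "resampling_report")
}

#' @exportS3Method base::print
print.resampling_report <- function(x, ...) {
  cat("Re-sampling report:", nrow(x$per_iteration), "iterations, positive =",
      x$config$positive_class, "\n")
  cat(sprintf("  averaged  SEN %.3f  SPC %.3f  ACC %.3f  MCC %.3f\n",
              x$averages$SEN, x$averages$SPC, x$averages$ACC, x$averages$MCC))
  invisible(x)
}

#' Write a re-sampling report (JSON + TSV summary + GMT signatures)
#'
#' @param report a `"resampling_report"`.
#' @param json_path full per-iteration report as JSON.
#' @param tsv_path optional per-iteration TSV.
#' @param gmt_path optional per-iteration selected-gene lists as GMT.
#' @return `json_path`, invisibly.
#' @export
write_resampling_report <- function(report, json_path, tsv_path = NULL,
                                    gmt_path = NULL) {
  out <- list(config = report$config,
              averages = report$averages,
              per_iteration = report$per_iteration,
              selected_genes = report$selected_genes)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(tsv_path))
    utils::write.table(report$per_iteration, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(gmt_path)) {
    lines <- vapply(seq_along(report$selected_genes), function(i)
      paste(c(paste0("iteration_", i), "svm_rfe",
              report$selected_genes[[i]]), collapse = "\t"), "")
    writeLines(lines, gmt_path)
  }
  invisible(json_path)
}
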