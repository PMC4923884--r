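#' Empirical covariance matrix across samples
#'
#' Computes the gene-by-gene covariance of an expression matrix.  The default
#' is the maximum-likelihood form (1/N normalisation), which is the `S` that
#' enters the penalised Gaussian log-likelihood; set `ml = FALSE` for the
#' unbiased 1/(N-1) version.
#'
#' @param mat numeric matrix, genes x samples (P x N).
#' @param ml divide by N (`TRUE`, default) or N-1 (`FALSE`).
#' @return a P x P symmetric positive semi-definite matrix with gene
#'   dimnames.
#' @export
empirical_covariance <- function(mat, ml = TRUE) {
  stopifnot(is.matrix(mat))
  n <- ncol(mat)
  if (n < 2L) stop("need at least 2 samples to estimate a covariance")
  xc <- mat - rowMeans(mat)
  s <- tcrossprod(xc) / (if (ml) n else n - 1L)
  s <- (s + t(s)) / 2
  dimnames(s) <- list(rownames(mat), rownames(mat))
  s
}

# value of log det theta - tr(S theta) - rho * ||theta||_1
glasso_objective <- function(theta, s, rho, penalize_diag = FALSE) {
  pen <- if (penalize_diag) sum(abs(theta)) else sum(abs(theta)) - sum(abs(diag(theta)))
  determinant(theta, logarithm = TRUE)$modulus[1L] -
    sum(s * theta) - rho * pen
}

# lasso subproblem by coordinate descent:
#   minimise 0.5 * b' V b - s12' b + rho * |b|_1   (V = W11, warm-started)
lasso_cd <- function(V, s12, rho, beta, tol, max_iter) {
  p <- length(s12)
  for (it in seq_len(max_iter)) {
    dmax <- 0
    for (j in seq_len(p)) {
      r <- s12[j] - sum(V[j, ] * beta) + V[j, j] * beta[j]
      bj <- sign(r) * max(abs(r) - rho, 0) / V[j, j]
      d <- abs(bj - beta[j])
      if (d > dmax) dmax <- d
      beta[j] <- bj
    }
    if (dmax < tol) break
  }
  beta
}

#' Sparse inverse covariance estimation (graphical lasso)
#'
#' Maximises the penalised Gaussian log-likelihood
#' \deqn{\log\det\theta - \mathrm{tr}(S\theta) - \rho\|\theta\|_1}
#' over positive-definite matrices \eqn{\theta} by blockwise coordinate
#' descent: each column's subproblem is an L1-penalised regression solved by
#' coordinate descent on the current working covariance.  Zero off-diagonal
#' entries of the estimate encode conditional independence between gene
#' pairs, so its support is the gene-gene network.
#'
#' By default only off-diagonal entries are penalised (the dominant solver
#' convention; diagonal entries of a precision matrix are never zero anyway);
#' `penalize_diag = TRUE` applies the letter-of-the-formula penalty to every
#' entry.
#'
#' @param S symmetric empirical covariance (P x P).
#' @param rho nonnegative L1 penalty.  `rho = 0` requires invertible `S` and
#'   returns the plain inverse.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   working covariance per sweep (scaled by the mean absolute off-diagonal
#'   of `S`).
#' @param max_iter maximum outer sweeps.
#' @param penalize_diag also penalise diagonal entries.
#' @return an object of class `"precision_estimate"`: list with `theta`
#'   (P x P precision estimate), `w` (its inverse, the working covariance),
#'   `rho`, `empirical_cov`, `converged`, `iterations`, `objective` and
#'   `penalize_diag`.
#' @export
#' @examples
#' S <- matrix(c(1, .5, .5, 1), 2, 2)
#' graphical_lasso(S, rho = 0)$theta     # = solve(S)
#' graphical_lasso(S, rho = 0.6)$theta   # diagonal: penalty kills the edge
graphical_lasso <- function(S, rho, tol = 1e-7, max_iter = 200L,
                            penalize_diag = FALSE) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("S must be symmetric")
  if (rho < 0) stop("rho must be nonnegative")
  p <- nrow(S)
  ids <- rownames(S) %||% as.character(seq_len(p))

  if (rho == 0) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev))
      stop("S is not invertible; rho = 0 requires an invertible covariance ",
           "(typically P <= N)")
    theta <- solve(S)
    theta <- (theta + t(theta)) / 2
    dimnames(theta) <- list(ids, ids)
    w <- S
    dimnames(w) <- dimnames(theta)
    return(structure(list(theta = theta, w = w, rho = 0,
                          empirical_cov = S, converged = TRUE,
                          iterations = 0L,
                          objective = glasso_objective(theta, S, 0, penalize_diag),
                          penalize_diag = penalize_diag),
                     class = "precision_estimate"))
  }

  W <- S
  diag(W) <- diag(S) + if (penalize_diag) rho else 0
  B <- matrix(0, p - 1L, p)           # per-column lasso coefficients
  off <- abs(S); diag(off) <- 0
  thr <- tol * max(mean(off), .Machine$double.eps)
  converged <- FALSE
  it <- 0L
  if (p == 1L) {
    converged <- TRUE
  } else {
    for (it in seq_len(max_iter)) {
      dmax <- 0
      for (j in seq_len(p)) {
        idx <- seq_len(p)[-j]
        V <- W[idx, idx, drop = FALSE]
        beta <- lasso_cd(V, S[idx, j], rho, B[, j], tol = thr / 10,
                         max_iter = 1000L)
        B[, j] <- beta
        w12 <- as.vector(V %*% beta)
        dmax <- max(dmax, max(abs(w12 - W[idx, j])))
        W[idx, j] <- w12
        W[j, idx] <- w12
      }
      if (dmax < thr) { converged <- TRUE; break }
    }
  }

  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    if (p == 1L) { theta[1L, 1L] <- 1 / W[1L, 1L]; break }
    idx <- seq_len(p)[-j]
    tjj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    theta[j, j] <- tjj
    theta[idx, j] <- -B[, j] * tjj
  }
  theta <- (theta + t(theta)) / 2
  dimnames(theta) <- list(ids, ids)
  dimnames(W) <- list(ids, ids)
  if (!converged)
    warning("graphical lasso did not converge in ", max_iter,
            " sweeps (rho = ", rho, "); result flagged")
  structure(list(theta = theta, w = W, rho = rho, empirical_cov = S,
                 converged = converged, iterations = it,
                 objective = glasso_objective(theta, S, rho, penalize_diag),
                 penalize_diag = penalize_diag),
            class = "precision_estimate")
}

#' @exportS3Method base::print
print.precision_estimate <- function(x, ...) {
  cat("Precision estimate: P =", nrow(x$theta),
      " rho =", x$rho,
      " converged =", x$converged,
      " objective =", format(x$objective, digits = 6), "\n")
  nz <- sum(abs(x$theta[upper.tri(x$theta)]) > 1e-8)
  cat("  nonzero off-diagonal pairs:", nz, "\n")
  invisible(x)
}
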