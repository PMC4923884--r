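# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: definitional double loops, exhaustive enumeration,
# a proximal-gradient solver, and hand-computed survival tables.

# covariance by the definitional double loop
cov_oracle <- function(mat, ml = TRUE) {
  p <- nrow(mat); n <- ncol(mat)
  s <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    mi <- mean(mat[i, ]); mj <- mean(mat[j, ])
    s[i, j] <- sum((mat[i, ] - mi) * (mat[j, ] - mj)) / (if (ml) n else n - 1)
  }
  s
}

# graphical lasso by proximal gradient (ISTA with backtracking) on the
# primal objective; slow but reaches ~1e-12, independent of the blockwise
# coordinate-descent solver in the package
ista_glasso <- function(S, rho, tol = 1e-12, max_iter = 200000L) {
  theta <- diag(1 / diag(S), nrow(S))
  soft <- function(m, l) { o <- sign(m) * pmax(abs(m) - l, 0); diag(o) <- diag(m); o }
  fsm <- function(th) {   # smooth part: -logdet + tr(S th)
    ch <- tryCatch(chol(th), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    -2 * sum(log(diag(ch))) + sum(S * th)
  }
  f <- fsm(theta)
  for (it in seq_len(max_iter)) {
    grad <- S - solve(theta)
    t <- 1; ok <- FALSE
    repeat {
      cand <- soft(theta - t * grad, t * rho)
      cand <- (cand + t(cand)) / 2
      fc <- fsm(cand)
      if (is.finite(fc) &&
          fc <= f + sum(grad * (cand - theta)) +
                sum((cand - theta)^2) / (2 * t) + 1e-14) { ok <- TRUE; break }
      t <- t / 2
      if (t < 1e-13) break
    }
    if (!ok) break
    d <- max(abs(cand - theta))
    theta <- cand; f <- fc
    if (d < tol) break
  }
  theta
}

# KKT stationarity violation of a candidate glasso solution
# (off-diagonal-only penalty): W = theta^-1 must satisfy
#   W_ij - S_ij = rho * sign(theta_ij)  where theta_ij != 0 (i != j)
#   |W_ij - S_ij| <= rho                where theta_ij  = 0 (i != j)
#   W_ii = S_ii
kkt_violation <- function(theta, S, rho, zero_tol = 1e-7) {
  W <- solve(theta)
  p <- nrow(theta)
  v <- max(abs(diag(W) - diag(S)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    d <- W[i, j] - S[i, j]
    if (abs(theta[i, j]) > zero_tol)
      v <- max(v, abs(d - rho * sign(theta[i, j])))
    else
      v <- max(v, max(abs(d) - rho, 0))
  }
  v
}

# brute-force confusion matrix + metrics from prediction/label vectors
metrics_oracle <- function(pred, truth, pos) {
  tp <- sum(pred == pos & truth == pos)
  tn <- sum(pred != pos & truth != pos)
  fp <- sum(pred == pos & truth != pos)
  fn <- sum(pred != pos & truth == pos)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       SEN = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       SPC = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ACC = (tp + tn) / length(truth),
       MCC = if (den > 0) (tp * tn - fp * fn) / sqrt(den) else NA_real_)
}

# two-group log-rank chi-square by the observed-minus-expected table
logrank_oe <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1L]
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(time[event]))) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(event & time == tt)
    d1 <- sum(event & time == tt & g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(statistic = chisq, p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

# exhaustive enumeration of seed module sets: all pairwise-disjoint index
# subsets of size >= 2, optionally reduced to maximal ones
seed_sets_oracle <- function(members_list, maximal = TRUE) {
  n <- length(members_list)
  all_sets <- list()
  for (k in 2:n) {
    for (cmb in utils::combn(n, k, simplify = FALSE)) {
      ok <- TRUE
      for (a in seq_len(k - 1)) for (b in seq(a + 1, k))
        if (length(intersect(members_list[[cmb[a]]],
                             members_list[[cmb[b]]])) > 0) ok <- FALSE
      if (ok) all_sets[[length(all_sets) + 1L]] <- cmb
    }
  }
  if (maximal && length(all_sets)) {
    keep <- vapply(seq_along(all_sets), function(i) {
      !any(vapply(seq_along(all_sets), function(j)
        i != j && all(all_sets[[i]] %in% all_sets[[j]]), TRUE))
    }, TRUE)
    all_sets <- all_sets[keep]
  }
  all_sets
}

# independent re-derivation of the overlap-greedy merge trace
merge_oracle <- function(seed_idx, mods) {
  cur <- lapply(mods[seed_idx], function(m) m$members)
  names(cur) <- vapply(mods[seed_idx], `[[`, "", "hub")
  sdeg <- vapply(mods[seed_idx], `[[`, 0, "hub_degree")
  rest_idx <- setdiff(seq_along(mods), seed_idx)
  rdeg <- vapply(mods[rest_idx], `[[`, 0, "hub_degree")
  rhub <- vapply(mods[rest_idx], `[[`, "", "hub")
  rest_idx <- rest_idx[order(-rdeg, rhub)]
  for (ri in rest_idx) {
    ov <- vapply(cur, function(m) length(intersect(mods[[ri]]$members, m)), 0)
    cand <- which(ov == max(ov))
    cand <- cand[order(-sdeg[cand], names(cur)[cand])]
    cur[[cand[1L]]] <- sort(union(cur[[cand[1L]]], mods[[ri]]$members))
  }
  lapply(cur, sort)
}

avg_overlap_oracle <- function(mods) {
  pairs <- utils::combn(length(mods), 2, simplify = FALSE)
  sum(vapply(pairs, function(p)
    length(intersect(mods[[p[1]]], mods[[p[2]]])), 0)) / length(pairs)
}
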