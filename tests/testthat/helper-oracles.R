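# Independent reference implementations used to cross-check the package.
# These are deliberately written as direct transcriptions of the
# definitions (brute-force pairwise recomputation each round) and stay
# independent of the code paths they verify.

oracle_sd <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

# Full stability ranking by brute force on a log2 matrix (rows named).
# Same declared tie-break: among equal elimination scores, the
# alphabetically later gene goes.
oracle_genorm <- function(lg, weights = NULL) {
  genes <- rownames(lg)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(genes)), genes)
  m_of <- function(set) {
    vapply(set, function(j) {
      mean(vapply(setdiff(set, j),
                  function(k) oracle_sd(lg[j, ] - lg[k, ]), numeric(1)))
    }, numeric(1))
  }
  remaining <- genes
  elim <- character()
  while (length(remaining) > 2) {
    M <- m_of(remaining)
    sc <- M / weights[remaining]
    tied <- remaining[sc == max(sc)]
    worst <- sort(tied)[length(tied)]
    elim <- c(elim, worst)
    remaining <- setdiff(remaining, worst)
  }
  ranking <- c(sort(remaining), rev(elim))
  V <- numeric(0)
  if (length(genes) > 2) {
    for (n in 2:(length(genes) - 1)) {
      nf_a <- apply(lg[ranking[1:n], , drop = FALSE], 2, mean)
      nf_b <- apply(lg[ranking[1:(n + 1)], , drop = FALSE], 2, mean)
      V <- c(V, oracle_sd(nf_a - nf_b))
    }
  }
  list(M = m_of(genes), elimination_order = elim, ranking = ranking,
       pairwise_variation = V)
}

# RUVg reference: explicit SVD of the centered control block plus
# normal-equations regression of all centered genes on W.
oracle_ruvg <- function(Y, ctrl_cols, k) {
  Xc <- scale(Y[, ctrl_cols, drop = FALSE], center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  W <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  alpha <- solve(t(W) %*% W, t(W) %*% Yc)
  list(W = W, alpha = alpha, corrected = Y - W %*% alpha)
}

# Random candidate matrix (strictly positive counts) for property suites.
random_candidate_dataset <- function(n_genes, n_lanes) {
  counts <- matrix(2^stats::rnorm(n_genes * n_lanes, 9, 1), n_genes, n_lanes)
  tiny_dataset(counts, names = sprintf("C%02d", seq_len(n_genes)))
}
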