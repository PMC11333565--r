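#' Median-of-ratios size factors
#'
#' The per-lane size factor is the median, over genes with strictly
#' positive counts in every lane, of the ratio of the lane's count to the
#' gene's geometric mean across lanes.  Counts are divided by the size
#' factor, removing lane-level depth differences; commonly used as a
#' pre-normalization before factor-based unwanted-variation removal.
#'
#' @param dataset a `CountDataset` on a counts scale.
#' @return list with `dataset` (rescaled) and `size_factors` (named
#'   per-lane vector of class `SizeFactors` with the per-gene reference in
#'   attribute `"reference"`).
#' @export
median_of_ratios <- function(dataset) {
  if (dataset$scale == "log2")
    stopf("median-of-ratios needs a dataset on a counts scale")
  m <- dataset$counts
  usable <- rowSums(m <= 0) == 0L
  if (!any(usable))
    stopf("no gene has positive counts in every lane")
  ref <- exp(rowMeans(log(m[usable, , drop = FALSE])))
  s <- apply(m[usable, , drop = FALSE] / ref, 2, stats::median)
  names(s) <- dataset$lanes$lane_id
  out <- set_counts(dataset, sweep(m, 2, s, `/`))
  list(dataset = out,
       size_factors = structure(s, reference = ref, class = "SizeFactors"))
}

#' Remove unwanted variation estimated from control genes (RUVg style)
#'
#' On the lanes x genes matrix `Y = log2(count + 0.5)`, the control-gene
#' submatrix is column-centered and decomposed by SVD; the unwanted
#' factors `W` are the first `k` left singular vectors scaled by their
#' singular values.  Loadings `alpha` are the least-squares regression of
#' all (column-centered) genes on `W`, and the corrected expression is
#' `Y - W alpha` with gene means restored.  Signs are fixed so that each
#' column of `W` has its largest-magnitude entry positive, making the
#' decomposition reproducible across linear-algebra backends.
#'
#' Controls with zero variance carry no information and are dropped with
#' a warning; if none remain the input is returned uncorrected.
#'
#' @param dataset a `CountDataset`.
#' @param control_genes names of negative-control or reference genes
#'   assumed unaffected by the biology of interest.
#' @param k number of unwanted factors, `1 <= k <= min(lanes, controls) - 1`.
#' @return Object of class `RuvModel`: `k`, `control_genes` (those used),
#'   `W` (lanes x k), `alpha` (k x genes), `corrected` (a `CountDataset`
#'   on the `log2` scale), `singular_values`.
#' @export
ruvg_fit <- function(dataset, control_genes, k) {
  idx <- match(control_genes, dataset$genes$name)
  if (anyNA(idx))
    stopf("control genes not in dataset: %s",
          paste(control_genes[is.na(idx)], collapse = ", "))
  Y <- t(as_log2(dataset))                      # lanes x genes
  n_lanes <- nrow(Y)
  ctrl <- Y[, idx, drop = FALSE]
  keep <- apply(ctrl, 2, sample_sd) > 0
  if (!all(keep))
    warnf("dropping %d zero-variance control gene(s)", sum(!keep))
  used <- control_genes[keep]
  if (length(used) == 0L) {
    warnf("no informative control genes; returning data uncorrected")
    corrected <- set_counts(dataset, as_log2(dataset), scale = "log2")
    return(structure(list(k = 0L, control_genes = character(),
                          W = matrix(0, n_lanes, 0), alpha = matrix(0, 0, ncol(Y)),
                          corrected = corrected, singular_values = numeric()),
                     class = "RuvModel"))
  }
  kmax <- min(n_lanes, length(used)) - 1L
  if (!is_scalar_number(k) || k < 1 || k > kmax)
    stopf("k must be in [1, %d] (lanes = %d, usable controls = %d)",
          kmax, n_lanes, length(used))
  ctrl <- ctrl[, keep, drop = FALSE]
  ctrl_c <- sweep(ctrl, 2, colMeans(ctrl))
  sv <- svd(ctrl_c)
  W <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  # sign convention: largest-|entry| of each factor positive
  for (j in seq_len(k)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  gene_means <- colMeans(Y)
  Yc <- sweep(Y, 2, gene_means)
  # W has orthogonal columns (scaled singular vectors), so the least-squares
  # loadings are W'Yc / d^2; factors beyond the control rank get zero loadings
  d2 <- sv$d[seq_len(k)]^2
  inv <- ifelse(d2 > max(sv$d^2) * 1e-24, 1 / d2, 0)
  alpha <- diag(inv, k, k) %*% crossprod(W, Yc)
  corrected_mat <- t(Y - W %*% alpha)           # genes x lanes, means retained
  corrected <- set_counts(dataset, corrected_mat, scale = "log2")
  structure(list(k = as.integer(k), control_genes = used, W = W, alpha = alpha,
                 corrected = corrected, singular_values = sv$d),
            class = "RuvModel")
}

#' @export
print.RuvModel <- function(x, ...) {
  cat(sprintf("RuvModel: k = %d, %d control genes, %d lanes\n",
              x$k, length(x$control_genes), nrow(x$W)))
  invisible(x)
}

#' Back-transform corrected log2 expression to the count scale
#'
#' @param model a `RuvModel`.
#' @return a `CountDataset` on the `corrected_counts` scale
#'   (`2^x - 0.5`, clamped at 0).
#' @export
ruv_counts <- function(model) {
  m <- pmax(2^model$corrected$counts - 0.5, 0)
  set_counts(model$corrected, m, scale = "corrected_counts")
}

#' Diagnostic scan over the number of unwanted factors
#'
#' Fits the control-gene factor model for `k = 1..k_max` and reports, per
#' k, the mean per-lane interquartile range of the corrected relative log
#' expression and the fraction of control-gene variance explained by the
#' k-th factor.  The table supports choosing k; no automatic choice is
#' made.
#'
#' @param dataset a `CountDataset`.
#' @param control_genes control gene names.
#' @param k_max largest k to scan.
#' @return data.frame with columns `k`, `mean_rle_iqr`,
#'   `variance_explained` (per-factor fraction).
#' @export
k_scan <- function(dataset, control_genes, k_max) {
  out <- data.frame(k = seq_len(k_max), mean_rle_iqr = NA_real_,
                    variance_explained = NA_real_)
  for (k in seq_len(k_max)) {
    fit <- ruvg_fit(dataset, control_genes, k)
    iqr <- iqr_summary(rle_matrix(fit$corrected))
    out$mean_rle_iqr[k] <- iqr$mean_iqr
    d2 <- fit$singular_values^2
    out$variance_explained[k] <- d2[k] / sum(d2)
  }
  out
}
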