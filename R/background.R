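#' Estimate per-lane background from negative controls
#'
#' Background for each lane is summarized from a set of source genes,
#' normally the panel's synthetic negative controls, optionally an
#' alternative set of low-expressed endogenous genes (see
#' [select_alternative_negatives()]).  Methods: per-lane `mean`,
#' `mean_plus_2sd` (mean + 2 sample SD, the common nCounter convention and
#' the default), `max`, `geomean`, or a `manual` constant applied to every
#' lane.
#'
#' @param dataset a `CountDataset` on a counts scale.
#' @param method background summary method.
#' @param source_genes gene names to summarize; defaults to all negative
#'   controls (ignored for `manual`).
#' @param manual_value constant threshold for `method = "manual"`.
#' @return Object of class `BackgroundEstimate`: list with `method`,
#'   `thresholds` (named per-lane vector), `source_genes`, `manual_value`.
#' @export
estimate_background <- function(dataset,
                                method = c("mean_plus_2sd", "mean", "max",
                                           "geomean", "manual"),
                                source_genes = NULL, manual_value = NULL) {
  method <- match.arg(method)
  n_lanes <- nrow(dataset$lanes)
  if (method == "manual") {
    if (!is_scalar_number(manual_value) || manual_value < 0)
      stopf("manual background needs a single non-negative manual_value")
    thr <- rep(manual_value, n_lanes)
    src <- character()
  } else {
    if (is.null(source_genes))
      source_genes <- dataset$genes$name[class_idx(dataset, "Negative")]
    if (length(source_genes) == 0L)
      stopf("no source genes for background method '%s'", method)
    missing <- setdiff(source_genes, dataset$genes$name)
    if (length(missing))
      stopf("background source genes not in dataset: %s",
            paste(missing, collapse = ", "))
    if (method == "mean_plus_2sd" && length(source_genes) < 2L)
      stopf("mean_plus_2sd needs at least 2 source genes")
    sub <- dataset$counts[match(source_genes, dataset$genes$name), , drop = FALSE]
    thr <- apply(sub, 2, switch(method,
      mean = mean,
      mean_plus_2sd = function(x) mean(x) + 2 * sample_sd(x),
      max = max,
      geomean = geomean))
    src <- source_genes
  }
  names(thr) <- dataset$lanes$lane_id
  structure(list(method = method, thresholds = thr,
                 source_genes = src, manual_value = manual_value),
            class = "BackgroundEstimate")
}

#' @export
print.BackgroundEstimate <- function(x, ...) {
  cat(sprintf("BackgroundEstimate (%s, %d source genes): thresholds %s\n",
              x$method, length(x$source_genes),
              paste(signif(x$thresholds, 4), collapse = ", ")))
  invisible(x)
}

#' Select alternative negative-control genes
#'
#' When the panel's negative controls behave poorly, low and stably
#' expressed endogenous genes can serve as a background proxy.  Among
#' endogenous genes with a cross-lane coefficient of variation at most
#' `max_cv`, the `n` genes with the lowest mean raw count are returned; if
#' fewer than `n` qualify the CV cap is relaxed (lowest-mean genes top up
#' the set) with a warning.  Ties are broken by gene name.
#'
#' @param dataset a `CountDataset`.
#' @param n number of genes to return (default 10).
#' @param max_cv coefficient-of-variation cap (default 0.5).
#' @return character vector of gene names.
#' @export
select_alternative_negatives <- function(dataset, n = 10, max_cv = 0.5) {
  if (!is_scalar_number(n) || n < 1) stopf("n must be >= 1")
  idx <- class_idx(dataset, "Endogenous")
  if (length(idx) < n)
    stopf("only %d endogenous genes, cannot select %d", length(idx), n)
  nm <- dataset$genes$name[idx]
  sub <- dataset$counts[idx, , drop = FALSE]
  mu <- rowMeans(sub)
  cv <- apply(sub, 1, coef_var)
  ord <- order_by_value_then_name(mu, nm)
  nm <- nm[ord]; mu <- mu[ord]; cv <- cv[ord]
  qualifying <- nm[cv <= max_cv]
  if (length(qualifying) >= n) return(qualifying[seq_len(n)])
  warnf("only %d endogenous genes meet cv <= %g; relaxing to lowest-mean genes",
        length(qualifying), max_cv)
  unique(c(qualifying, nm))[seq_len(n)]
}

#' Apply background correction
#'
#' Modes: `subtract` (`max(count - b, 0)`), `floor` (`max(count, b)`), or
#' `skip` (no change).  The resulting dataset is tagged
#' `corrected_counts`.
#'
#' @param dataset a `CountDataset` on a counts scale.
#' @param background a `BackgroundEstimate` for the same lanes.
#' @param mode correction mode.
#' @return corrected `CountDataset`.
#' @export
correct_background <- function(dataset, background,
                               mode = c("subtract", "floor", "skip")) {
  mode <- match.arg(mode)
  if (dataset$scale == "log2")
    stopf("background correction needs a dataset on a counts scale")
  if (mode == "skip") return(dataset)
  if (!inherits(background, "BackgroundEstimate"))
    stopf("background must be a BackgroundEstimate")
  b <- background$thresholds
  if (length(b) != ncol(dataset$counts))
    stopf("background has %d lanes, dataset has %d", length(b), ncol(dataset$counts))
  m <- dataset$counts
  for (j in seq_len(ncol(m))) {
    m[, j] <- if (mode == "subtract") pmax(m[, j] - b[j], 0) else pmax(m[, j], b[j])
  }
  set_counts(dataset, m, scale = "corrected_counts")
}
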