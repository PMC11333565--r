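#' Relative log expression matrix
#'
#' On `log2(count + 0.5)` (or the values as-is for a dataset already on
#' the log2 scale), restricted to endogenous genes by default (controls
#' would dilute the diagnostic), each gene's median across lanes is
#' subtracted.  Tight, zero-centered per-lane distributions indicate
#' successful normalization.
#'
#' @param dataset a `CountDataset`.
#' @param genes `"endogenous"` (default) or `"all"`.
#' @return genes x lanes numeric matrix; every row has median 0.
#' @export
rle_matrix <- function(dataset, genes = c("endogenous", "all")) {
  genes <- match.arg(genes)
  m <- as_log2(dataset)
  if (genes == "endogenous") {
    idx <- class_idx(dataset, "Endogenous")
    if (length(idx) == 0L) stopf("no endogenous genes for RLE")
    m <- m[idx, , drop = FALSE]
  }
  m - apply(m, 1, stats::median)
}

#' Per-lane interquartile range of relative log expression
#'
#' @param rle RLE matrix from [rle_matrix()] (at least 4 genes for a
#'   meaningful quartile).
#' @return list with `lane_iqr` (named per-lane IQR, linear-interpolation
#'   quantiles, type 7) and `mean_iqr`.
#' @export
iqr_summary <- function(rle) {
  if (nrow(rle) < 4L) warnf("fewer than 4 genes; IQR is a coarse summary")
  lane_iqr <- apply(rle, 2, stats::IQR, type = 7)
  list(lane_iqr = lane_iqr, mean_iqr = mean(lane_iqr))
}

#' Principal component scores of the lanes
#'
#' Singular value decomposition of the gene-centered log2 endogenous
#' matrix; lane scores for the requested components plus the fraction of
#' variance each explains.  Component signs are fixed so the
#' largest-magnitude score of each component is positive.
#'
#' @param dataset a `CountDataset` (at least 3 lanes).
#' @param components number of components (at most `lanes - 1`).
#' @return list with `scores` (lanes x components), `variance_explained`,
#'   and `degenerate` (TRUE when the lanes are identical).
#' @export
pca_lanes <- function(dataset, components = 2) {
  n_lanes <- ncol(dataset$counts)
  if (n_lanes < 3L) stopf("PCA needs at least 3 lanes")
  if (components > n_lanes - 1L)
    stopf("components = %d exceeds lanes - 1 = %d", components, n_lanes - 1L)
  idx <- class_idx(dataset, "Endogenous")
  m <- as_log2(dataset)
  if (length(idx) > 0L) m <- m[idx, , drop = FALSE]
  mc <- m - rowMeans(m)
  sv <- svd(mc)
  d2 <- sv$d^2
  degenerate <- sum(d2) < 1e-12
  ve <- if (degenerate) rep(0, components) else (d2 / sum(d2))[seq_len(components)]
  scores <- sv$v[, seq_len(components), drop = FALSE] %*%
    diag(sv$d[seq_len(components)], components, components)
  for (j in seq_len(components)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- dataset$lanes$sample_id
  colnames(scores) <- sprintf("PC%d", seq_len(components))
  list(scores = scores, variance_explained = ve, degenerate = degenerate)
}

#' Summarize a dataset for normalization-quality evaluation
#'
#' @param dataset a `CountDataset`.
#' @param components PCA components to keep.
#' @return Object of class `EvaluationSummary`: `rle`, `lane_iqr`,
#'   `mean_iqr`, `pca`, `labels` (group/batch per lane).
#' @export
evaluation_summary <- function(dataset, components = 2) {
  r <- rle_matrix(dataset)
  iqr <- iqr_summary(r)
  p <- if (ncol(dataset$counts) >= 3L) pca_lanes(dataset, components) else NULL
  structure(list(rle = r, lane_iqr = iqr$lane_iqr, mean_iqr = iqr$mean_iqr,
                 pca = p,
                 labels = dataset$lanes[, c("sample_id", "group", "batch")]),
            class = "EvaluationSummary")
}

#' Compare raw and normalized data
#'
#' Computes evaluation summaries for both datasets and a verdict:
#' `"improved"` when the normalized mean RLE IQR is below the raw one,
#' `"worsened"` when above, `"unchanged"` at (numerical) equality.
#' Optionally writes an RLE boxplot panel and PCA scatter plots (colored
#' by group and batch) as PNG files.
#'
#' @param raw a `CountDataset` of raw counts.
#' @param normalized the same lanes after normalization.
#' @param out_dir optional directory for plot files.
#' @return list of class `NormComparison`: `raw`, `normalized`
#'   (`EvaluationSummary` each), `verdict`, `plots` (paths or NULL).
#' @export
compare_normalization <- function(raw, normalized, out_dir = NULL) {
  if (!identical(raw$lanes$lane_id, normalized$lanes$lane_id))
    stopf("raw and normalized datasets have different lanes")
  s_raw <- evaluation_summary(raw)
  s_norm <- evaluation_summary(normalized)
  eps <- 1e-12
  verdict <- if (s_norm$mean_iqr < s_raw$mean_iqr - eps) "improved"
             else if (s_norm$mean_iqr > s_raw$mean_iqr + eps) "worsened"
             else "unchanged"
  plots <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    plots <- c(rle = file.path(out_dir, "rle.png"),
               pca = file.path(out_dir, "pca.png"))
    grDevices::png(plots[["rle"]], width = 1400, height = 600)
    graphics::par(mfrow = c(1, 2))
    plot_rle(s_raw, main = "RLE, raw")
    plot_rle(s_norm, main = "RLE, normalized")
    grDevices::dev.off()
    if (!is.null(s_raw$pca)) {
      grDevices::png(plots[["pca"]], width = 1400, height = 600)
      graphics::par(mfrow = c(1, 2))
      plot_pca(s_raw, color_by = "batch", main = "PCA, raw (by batch)")
      plot_pca(s_norm, color_by = "group", main = "PCA, normalized (by group)")
      grDevices::dev.off()
    } else {
      plots <- plots["rle"]
    }
  }
  structure(list(raw = s_raw, normalized = s_norm, verdict = verdict,
                 plots = plots),
            class = "NormComparison")
}

#' @export
print.NormComparison <- function(x, ...) {
  cat(sprintf("mean RLE IQR: raw %.4f -> normalized %.4f (%s)\n",
              x$raw$mean_iqr, x$normalized$mean_iqr, x$verdict))
  invisible(x)
}

#' RLE boxplot panel
#' @param summary an `EvaluationSummary`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot_rle <- function(summary, ...) {
  graphics::boxplot(summary$rle, outline = FALSE, las = 2,
                    ylab = "relative log2 expression", ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
}

#' PCA scatter of lane scores
#' @param summary an `EvaluationSummary` with a PCA component.
#' @param color_by `"group"` or `"batch"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_pca <- function(summary, color_by = c("group", "batch"), ...) {
  color_by <- match.arg(color_by)
  if (is.null(summary$pca)) stopf("no PCA in this summary")
  lab <- summary$labels[[color_by]]
  lab[is.na(lab)] <- "NA"
  cols <- as.integer(factor(lab))
  s <- summary$pca$scores
  ve <- summary$pca$variance_explained
  graphics::plot(s[, 1], s[, 2], col = cols, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * ve[2]), ...)
  graphics::legend("topright", legend = levels(factor(lab)),
                   col = seq_along(levels(factor(lab))), pch = 19)
}
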