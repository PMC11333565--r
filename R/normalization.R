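#' Per-lane scaling factors from a sample-derived statistic
#'
#' Generic scaling engine behind both technical (positive-control) and
#' content (reference-gene) normalization.  For each lane a summary
#' statistic is computed (geometric mean of a gene set, total counts, or
#' the geometric mean of the top-n most expressed endogenous genes) and the
#' lane factor is `target / statistic_i`, where the target is the
#' arithmetic mean of the per-lane statistics (geometric-mean target
#' available via `target`).  Applying the factors equalizes the statistic
#' across lanes.
#'
#' @param dataset a `CountDataset`.
#' @param statistic `"genes"` (geometric mean of `genes`), `"total"`
#'   (sum of all counts) or `"topn"` (geometric mean of the `topn` most
#'   expressed endogenous genes, ranked by mean count).
#' @param genes gene names when `statistic = "genes"`.
#' @param topn number of endogenous genes for `statistic = "topn"`.
#' @param target `"arithmetic"` (default) or `"geometric"` mean of the
#'   per-lane statistics.
#' @param kind label recorded on the result (`"technical"` or `"content"`).
#' @return Object of class `ScalingFactors`: data.frame with `lane_id`,
#'   `statistic`, `factor`; attributes `kind` and `reference_statistic`.
#' @export
scaling_factors <- function(dataset,
                            statistic = c("genes", "total", "topn"),
                            genes = NULL, topn = 10,
                            target = c("arithmetic", "geometric"),
                            kind = "content") {
  statistic <- match.arg(statistic)
  target <- match.arg(target)
  if (statistic == "genes") {
    if (is.null(genes) || length(genes) == 0L)
      stopf("statistic 'genes' needs a non-empty gene set")
    missing <- setdiff(genes, dataset$genes$name)
    if (length(missing))
      stopf("genes not in dataset: %s", paste(missing, collapse = ", "))
    sub <- dataset$counts[match(genes, dataset$genes$name), , drop = FALSE]
    s <- apply(sub, 2, geomean)
    desc <- sprintf("geomean of %d genes", length(genes))
  } else if (statistic == "total") {
    s <- colSums(dataset$counts)
    desc <- "total counts"
  } else {
    idx <- class_idx(dataset, "Endogenous")
    if (length(idx) < topn)
      stopf("only %d endogenous genes, cannot take top %d", length(idx), topn)
    mu <- rowMeans(dataset$counts[idx, , drop = FALSE])
    nm <- dataset$genes$name[idx]
    top <- nm[order(-mu, nm, method = "radix")][seq_len(topn)]
    sub <- dataset$counts[match(top, dataset$genes$name), , drop = FALSE]
    s <- apply(sub, 2, geomean)
    desc <- sprintf("geomean of top-%d endogenous", topn)
  }
  if (any(!is.finite(s)) || any(s <= 0))
    stopf("degenerate per-lane statistic (zero or non-finite) in lane %s",
          paste(dataset$lanes$lane_id[!is.finite(s) | s <= 0], collapse = ", "))
  tgt <- if (target == "arithmetic") mean(s) else exp(mean(log(s)))
  out <- data.frame(lane_id = dataset$lanes$lane_id, statistic = unname(s),
                    factor = unname(tgt / s), stringsAsFactors = FALSE)
  structure(out, kind = kind, reference_statistic = desc,
            class = c("ScalingFactors", "data.frame"))
}

apply_factors <- function(dataset, factors) {
  m <- sweep(dataset$counts, 2, factors$factor, `*`)
  set_counts(dataset, m)
}

#' Technical normalization by positive-control scaling
#'
#' Multiplies every count in lane i by the positive scaling factor
#' `mean_of_lane_geomeans / lane_geomean_i` computed from the
#' positive-control probes (the same formula reported by QC).  After
#' normalization the positive geometric means are equal across lanes
#' (relative spread below 1e-9).
#'
#' @param dataset a `CountDataset` on a counts scale.
#' @return list with elements `dataset` (normalized) and `factors`
#'   (`ScalingFactors`, kind `"technical"`).
#' @export
technical_normalize <- function(dataset) {
  pos <- class_counts(dataset, "Positive")
  if (nrow(pos) < 1L) stopf("no positive controls in dataset")
  zero <- colSums(pos > 0) == 0
  if (any(zero))
    stopf("all positive controls are zero in lane %s",
          paste(dataset$lanes$lane_id[zero], collapse = ", "))
  f <- scaling_factors(dataset, statistic = "genes",
                       genes = dataset$genes$name[class_idx(dataset, "Positive")],
                       kind = "technical")
  out <- apply_factors(dataset, f)
  g <- f$statistic * f$factor  # scaled positive geomean, zero-floor convention
  if (diff(range(g)) / mean(g) > 1e-9)
    stopf("positive geomeans not equalized (internal error)")
  list(dataset = out, factors = f)
}

#' Content normalization by reference genes
#'
#' Scales every lane so the geometric mean of the chosen reference genes
#' (or an alternative sample-derived statistic: total counts, top-n most
#' expressed endogenous, or all endogenous genes) is equal across lanes.
#'
#' @param dataset a `CountDataset` on a counts scale.
#' @param reference_genes character vector of reference gene names
#'   (required for `statistic = "refgenes"`).
#' @param statistic `"refgenes"`, `"total"`, `"topn"` or `"all_endo"`.
#' @param topn top-n size when `statistic = "topn"`.
#' @return list with `dataset` and `factors` (kind `"content"`).
#' @export
content_normalize <- function(dataset, reference_genes = NULL,
                              statistic = c("refgenes", "total", "topn",
                                            "all_endo"),
                              topn = 10) {
  statistic <- match.arg(statistic)
  f <- switch(statistic,
    refgenes = {
      if (is.null(reference_genes) || length(reference_genes) == 0L)
        stopf("content normalization needs a non-empty reference gene set")
      scaling_factors(dataset, "genes", genes = reference_genes, kind = "content")
    },
    total = scaling_factors(dataset, "total", kind = "content"),
    topn = scaling_factors(dataset, "topn", topn = topn, kind = "content"),
    all_endo = scaling_factors(dataset, "genes",
                               genes = dataset$genes$name[class_idx(dataset, "Endogenous")],
                               kind = "content")
  )
  list(dataset = apply_factors(dataset, f), factors = f)
}

#' Per-lane regression calibration against the positive ladder
#'
#' For each lane, ordinary least squares of `log2(count + 0.5)` on
#' `log2(known_concentration)` over the positive-control ladder; every
#' gene's calibrated value is `(log2(count + 0.5) - intercept) / slope`,
#' i.e. expression mapped onto the concentration axis.  Unlike a single
#' scaling factor, the per-lane slope also corrects compression or
#' expansion of the dynamic range.  The output dataset is on the `log2`
#' scale.
#'
#' @param dataset a `CountDataset` on a counts scale.
#' @return list with `dataset` (calibrated, scale `log2`) and
#'   `calibration` (data.frame `lane_id`, `slope`, `intercept`, `r2`).
#' @export
regression_calibrate <- function(dataset) {
  idx <- class_idx(dataset, "Positive")
  conc <- dataset$genes$known_concentration[idx]
  keep <- !is.na(conc)
  if (sum(keep) < 3L) stopf("need >= 3 positives with known concentration")
  x <- log2(conc[keep])
  n <- nrow(dataset$lanes)
  slope <- intercept <- r2 <- numeric(n)
  for (j in seq_len(n)) {
    y <- log2p(dataset$counts[idx[keep], j])
    fit <- stats::lm.fit(cbind(1, x), y)
    a <- fit$coefficients[2]
    if (!is.finite(a) || abs(a) < 1e-6)
      stopf("flat positive ladder in lane %s (slope %g)",
            dataset$lanes$lane_id[j], a)
    slope[j] <- a
    intercept[j] <- fit$coefficients[1]
    r2[j] <- if (sample_sd(y) == 0) 0 else stats::cor(x, y)^2
  }
  m <- log2p(dataset$counts)
  for (j in seq_len(n)) m[, j] <- (m[, j] - intercept[j]) / slope[j]
  list(dataset = set_counts(dataset, m, scale = "log2"),
       calibration = data.frame(lane_id = dataset$lanes$lane_id,
                                slope = slope, intercept = intercept, r2 = r2,
                                stringsAsFactors = FALSE))
}

#' Gene-wise standardization
#'
#' Converts to the log2 scale if needed, then centers every gene to mean 0
#' and scales to sample SD 1 across lanes.  Constant genes become all-zero
#' rows and are recorded in the `"constant_genes"` attribute.
#'
#' @param dataset a `CountDataset`.
#' @return standardized `CountDataset` on the `log2` scale.
#' @export
standardize <- function(dataset) {
  m <- as_log2(dataset)
  mu <- rowMeans(m)
  sd <- apply(m, 1, sample_sd)
  const <- sd == 0
  sd[const] <- 1
  m <- (m - mu) / sd
  m[const, ] <- 0
  out <- set_counts(dataset, m, scale = "log2")
  attr(out, "constant_genes") <- dataset$genes$name[const]
  out
}
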