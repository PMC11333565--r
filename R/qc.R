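#' Quality-control acceptance thresholds
#'
#' All five lane QC metrics are compared against configurable ranges; the
#' defaults follow common nCounter practice: at least 75% of fields of view
#' imaged, binding density within 0.1-2.25 spots/um2, positive-control
#' linearity R2 of at least 0.95, positive scaling factor within 0.3-3, and
#' at most 80% of endogenous genes below background.
#'
#' @param fov_min_pct minimum imaged-FOV percentage.
#' @param bd_range binding-density acceptance interval (spots/um2).
#' @param linearity_min_r2 minimum positive-control R2.
#' @param positive_scaling_range scaling-factor acceptance interval.
#' @param below_bg_max_pct maximum percentage of endogenous genes below
#'   background.
#' @return list of class `QcThresholds`.
#' @export
qc_thresholds <- function(fov_min_pct = 75, bd_range = c(0.1, 2.25),
                          linearity_min_r2 = 0.95,
                          positive_scaling_range = c(0.3, 3),
                          below_bg_max_pct = 80) {
  stopifnot(length(bd_range) == 2L, bd_range[1] <= bd_range[2],
            length(positive_scaling_range) == 2L,
            positive_scaling_range[1] <= positive_scaling_range[2],
            fov_min_pct >= 0, fov_min_pct <= 100,
            below_bg_max_pct >= 0, below_bg_max_pct <= 100,
            all(is.finite(c(fov_min_pct, bd_range, linearity_min_r2,
                            positive_scaling_range, below_bg_max_pct))))
  structure(list(fov_min_pct = fov_min_pct, bd_range = bd_range,
                 linearity_min_r2 = linearity_min_r2,
                 positive_scaling_range = positive_scaling_range,
                 below_bg_max_pct = below_bg_max_pct),
            class = "QcThresholds")
}

#' Imaged field-of-view percentage
#'
#' @param lane one-row lane data.frame (from a `CountDataset`'s `lanes`).
#' @return `100 * fov_counted / fov_count`, or `NA` if the attributes are
#'   absent or `fov_count` is zero.
#' @export
fov_metric <- function(lane) {
  fc <- lane$fov_count
  fd <- lane$fov_counted
  if (is.na(fc) || is.na(fd) || fc <= 0) return(NA_real_)
  100 * fd / fc
}

#' Positive-control linearity
#'
#' Squared Pearson correlation between `log2(count + 0.5)` and
#' `log2(known_concentration)` over the positive-control ladder in one
#' lane.  The lowest ladder point (0.125 fM by default) sits near
#' background in standard panels and is excluded unless
#' `exclude_conc = NULL`.
#'
#' @param dataset a `CountDataset`.
#' @param lane lane index.
#' @param exclude_conc ladder concentrations to drop (default 0.125 fM).
#' @return R2 in `[0, 1]`; `NA` if fewer than 3 usable positives; 0 when
#'   counts are constant across the ladder.
#' @export
linearity_metric <- function(dataset, lane, exclude_conc = 0.125) {
  idx <- class_idx(dataset, "Positive")
  conc <- dataset$genes$known_concentration[idx]
  keep <- !is.na(conc)
  if (!is.null(exclude_conc)) keep <- keep & !(conc %in% exclude_conc)
  if (sum(keep) < 3L) return(NA_real_)
  y <- log2p(dataset$counts[idx[keep], lane])
  x <- log2(conc[keep])
  if (sample_sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Positive-control scaling factors
#'
#' Per-lane technical scaling factor: the arithmetic mean over lanes of the
#' geometric mean of positive-control counts, divided by the lane's own
#' positive geometric mean (zeros replaced by 0.5 before the geometric
#' mean).  Factors far from 1 indicate lane-level technical variation.
#'
#' @param dataset a `CountDataset`.
#' @return named numeric vector of per-lane factors (`Inf` for a lane whose
#'   positives are all zero).
#' @export
scaling_factor_metric <- function(dataset) {
  pos <- class_counts(dataset, "Positive")
  if (nrow(pos) < 1L) stopf("no positive controls in dataset")
  g <- apply(pos, 2, geomean)
  all_zero <- colSums(pos > 0) == 0
  f <- mean(g) / g
  f[all_zero] <- Inf
  names(f) <- dataset$lanes$lane_id
  f
}

#' Percentage of endogenous genes below background
#'
#' @param dataset a `CountDataset`.
#' @param background a `BackgroundEstimate`.
#' @return named per-lane percentage of endogenous genes whose count is
#'   strictly below the lane's background threshold.
#' @export
below_background_metric <- function(dataset, background) {
  endo <- class_counts(dataset, "Endogenous")
  if (nrow(endo) == 0L) stopf("no endogenous genes in dataset")
  b <- background$thresholds
  pct <- vapply(seq_len(ncol(endo)),
                function(j) 100 * mean(endo[, j] < b[j]), numeric(1))
  names(pct) <- dataset$lanes$lane_id
  pct
}

#' Run lane quality control
#'
#' Computes the five lane metrics (FOV percentage, binding density read
#' from the lane attributes, positive-control linearity, positive scaling
#' factor, percentage of endogenous genes below background), flags every
#' value outside its threshold (an unavailable metric always flags), and
#' suggests removal of any lane with at least one flag.
#'
#' @param dataset a `CountDataset`.
#' @param thresholds a `QcThresholds`.
#' @param background a `BackgroundEstimate` (default: mean + 2 SD of the
#'   negative controls).
#' @return Object of class `QcReport`: `metrics` data.frame, per-lane
#'   `flags` list, `pass` logicals, `suggested_removals`, `thresholds`.
#' @export
run_qc <- function(dataset, thresholds = qc_thresholds(),
                   background = estimate_background(dataset)) {
  validate_dataset(dataset)
  n <- nrow(dataset$lanes)
  metrics <- data.frame(
    lane_id = dataset$lanes$lane_id,
    sample_id = dataset$lanes$sample_id,
    fov_pct = vapply(seq_len(n), function(i) fov_metric(dataset$lanes[i, ]), numeric(1)),
    binding_density = dataset$lanes$binding_density,
    linearity_r2 = vapply(seq_len(n), function(i) linearity_metric(dataset, i), numeric(1)),
    positive_scaling_factor = unname(scaling_factor_metric(dataset)),
    pct_below_background = unname(below_background_metric(dataset, background)),
    stringsAsFactors = FALSE
  )
  out_of <- function(v, lo, hi) is.na(v) | !is.finite(v) | v < lo | v > hi
  flag_tbl <- cbind(
    fov_pct = out_of(metrics$fov_pct, thresholds$fov_min_pct, Inf),
    binding_density = out_of(metrics$binding_density,
                             thresholds$bd_range[1], thresholds$bd_range[2]),
    linearity_r2 = out_of(metrics$linearity_r2, thresholds$linearity_min_r2, Inf),
    positive_scaling_factor = out_of(metrics$positive_scaling_factor,
                                     thresholds$positive_scaling_range[1],
                                     thresholds$positive_scaling_range[2]),
    pct_below_background = out_of(metrics$pct_below_background,
                                  0, thresholds$below_bg_max_pct)
  )
  flags <- lapply(seq_len(n), function(i) colnames(flag_tbl)[flag_tbl[i, ]])
  names(flags) <- metrics$lane_id
  pass <- vapply(flags, function(f) length(f) == 0L, logical(1))
  structure(list(metrics = metrics, flags = flags, pass = pass,
                 suggested_removals = metrics$lane_id[!pass],
                 thresholds = thresholds),
            class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QcReport: %d lanes, %d pass\n", length(x$pass), sum(x$pass)))
  print(cbind(x$metrics,
              flags = vapply(x$flags, paste, character(1), collapse = ";")),
        digits = 4)
  if (length(x$suggested_removals))
    cat("suggested removals:", paste(x$suggested_removals, collapse = ", "), "\n")
  invisible(x)
}

#' Write a QC report to JSON and/or a minimal HTML page
#'
#' @param report a `QcReport`.
#' @param json optional JSON output path.
#' @param html optional HTML output path.
#' @return invisible list of written paths.
#' @export
write_qc_report <- function(report, json = NULL, html = NULL) {
  obj <- list(
    thresholds = unclass(report$thresholds),
    lanes = lapply(seq_len(nrow(report$metrics)), function(i) {
      row <- report$metrics[i, ]
      c(as.list(row), list(flags = I(report$flags[[i]]),
                           pass = unname(report$pass[i])))
    }),
    suggested_removals = I(report$suggested_removals)
  )
  if (!is.null(json))
    jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(html)) {
    m <- report$metrics
    cells <- function(v) paste(sprintf("<td>%s</td>", v), collapse = "")
    rows <- vapply(seq_len(nrow(m)), function(i) {
      sprintf("<tr%s>%s</tr>",
              if (report$pass[i]) "" else ' class="flagged"',
              cells(c(m$lane_id[i], m$sample_id[i],
                      signif(unlist(m[i, 3:7]), 5),
                      paste(report$flags[[i]], collapse = "; "))))
    }, character(1))
    page <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
              "<title>Lane QC report</title>",
              "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px}",
              ".flagged{background:#fdd}</style></head><body>",
              "<h1>Lane QC report</h1><table><tr>",
              paste(sprintf("<th>%s</th>",
                            c("lane", "sample", "FOV %", "binding density",
                              "linearity R2", "scaling factor", "% below bg",
                              "flags")), collapse = ""),
              "</tr>", rows, "</table>",
              sprintf("<p>Suggested removals: %s</p>",
                      if (length(report$suggested_removals))
                        paste(report$suggested_removals, collapse = ", ")
                      else "none"),
              "</body></html>")
    writeLines(page, html)
  }
  invisible(list(json = json, html = html))
}

#' Drop lanes from a dataset
#'
#' @param dataset a `CountDataset`.
#' @param lane_ids lane ids to remove.
#' @return dataset without those lanes (gene table unchanged).  At least 2
#'   lanes must remain, the minimum every downstream stage needs.
#' @export
drop_lanes <- function(dataset, lane_ids) {
  if (length(lane_ids) == 0L) return(dataset)
  unknown <- setdiff(lane_ids, dataset$lanes$lane_id)
  if (length(unknown))
    stopf("unknown lane id(s): %s", paste(unknown, collapse = ", "))
  keep <- !(dataset$lanes$lane_id %in% lane_ids)
  if (sum(keep) < 2L)
    stopf("cannot drop to fewer than 2 lanes (%d would remain)", sum(keep))
  subset_lanes(dataset, which(keep))
}
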