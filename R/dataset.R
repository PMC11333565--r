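#' Annotated nCounter count dataset
#'
#' The central container used by every stage of the package: a genes x lanes
#' table of non-negative values, a gene annotation table carrying the code
#' class of every probe (positive/negative synthetic controls, housekeeping,
#' endogenous targets), and a lane annotation table carrying the instrument
#' attributes consumed by quality control plus optional condition group and
#' batch labels.
#'
#' Values are stored as doubles so that corrected and normalized data reuse
#' the same container; the `scale` tag (`"raw_counts"`, `"corrected_counts"`
#' or `"log2"`) disambiguates what the numbers mean.
#'
#' @param genes data.frame with columns `name`, `accession`, `code_class`,
#'   `known_concentration` (fM, `NA` except for positive controls).
#' @param lanes data.frame with columns `lane_id`, `sample_id`, `fov_count`,
#'   `fov_counted`, `binding_density`, `cartridge_id`, `group`, `batch`.
#' @param counts numeric matrix, `nrow(genes)` x `nrow(lanes)`.
#' @param scale one of `"raw_counts"`, `"corrected_counts"`, `"log2"`.
#' @return An object of class `CountDataset`.
#' @export
count_dataset <- function(genes, lanes, counts,
                          scale = c("raw_counts", "corrected_counts", "log2")) {
  scale <- match.arg(scale)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  lanes <- as.data.frame(lanes, stringsAsFactors = FALSE)
  for (col in c("group", "batch")) {
    if (is.null(lanes[[col]])) lanes[[col]] <- NA_character_
  }
  if (is.null(genes$known_concentration)) genes$known_concentration <- NA_real_
  if (is.null(genes$accession)) genes$accession <- NA_character_
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  rownames(counts) <- genes$name
  colnames(counts) <- lanes$sample_id
  x <- structure(
    list(genes = genes, lanes = lanes, counts = counts, scale = scale),
    class = "CountDataset"
  )
  validate_dataset(x)
  x
}

#' Validate a CountDataset
#'
#' Checks the structural invariants: matching dimensions, unique gene and
#' lane identifiers, non-negative values on count scales, positive known
#' concentrations, and consistent field-of-view attributes.
#'
#' @param x a `CountDataset`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_dataset <- function(x) {
  if (!inherits(x, "CountDataset")) stopf("not a CountDataset")
  if (nrow(x$counts) != nrow(x$genes))
    stopf("count rows (%d) do not match gene table (%d)",
          nrow(x$counts), nrow(x$genes))
  if (ncol(x$counts) != nrow(x$lanes))
    stopf("count columns (%d) do not match lane table (%d)",
          ncol(x$counts), nrow(x$lanes))
  if (any(!nzchar(x$genes$name))) stopf("empty gene name")
  if (anyDuplicated(x$genes$name))
    stopf("duplicate gene names: %s",
          paste(unique(x$genes$name[duplicated(x$genes$name)]), collapse = ", "))
  if (anyDuplicated(x$lanes$lane_id))
    stopf("duplicate lane_id: %s",
          paste(unique(x$lanes$lane_id[duplicated(x$lanes$lane_id)]), collapse = ", "))
  kc <- x$genes$known_concentration
  if (any(!is.na(kc) & kc <= 0)) stopf("known_concentration must be > 0")
  if (x$scale != "log2" && any(x$counts < 0))
    stopf("negative values in a dataset on scale '%s'", x$scale)
  fov_bad <- !is.na(x$lanes$fov_count) & !is.na(x$lanes$fov_counted) &
    (x$lanes$fov_counted > x$lanes$fov_count | x$lanes$fov_counted < 0)
  if (any(fov_bad))
    stopf("fov_counted outside [0, fov_count] for lane %s",
          x$lanes$lane_id[which(fov_bad)[1]])
  invisible(x)
}

#' @export
print.CountDataset <- function(x, ...) {
  cls <- table(code_class_of(x))
  cat(sprintf("CountDataset: %d genes x %d lanes (scale: %s)\n",
              nrow(x$genes), nrow(x$lanes), x$scale))
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  grp <- x$lanes$group
  if (any(!is.na(grp)))
    cat("  groups: ", paste(sprintf("%s=%d", names(table(grp)), table(grp)),
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.CountDataset <- function(x) dim(x$counts)

# Canonical code-class labels; vendor files vary in case and suffixes
# ("Endogenous1" etc.), so match on a case-insensitive prefix.
canonical_code_class <- function(cc) {
  out <- as.character(cc)
  low <- tolower(out)
  out[startsWith(low, "positive")] <- "Positive"
  out[startsWith(low, "negative")] <- "Negative"
  out[startsWith(low, "housekeeping")] <- "Housekeeping"
  out[startsWith(low, "endogenous")] <- "Endogenous"
  out
}

code_class_of <- function(dataset) canonical_code_class(dataset$genes$code_class)

# Row indices of a code class
class_idx <- function(dataset, class) which(code_class_of(dataset) == class)

# Counts of one code class, kept as a matrix even for a single gene
class_counts <- function(dataset, class) {
  dataset$counts[class_idx(dataset, class), , drop = FALSE]
}

# Dataset values on the log2 scale (with pseudo-count where needed)
as_log2 <- function(dataset) {
  if (dataset$scale == "log2") dataset$counts else log2p(dataset$counts)
}

# Replace the count matrix, optionally retagging the scale
set_counts <- function(dataset, counts, scale = dataset$scale) {
  dataset$counts <- counts
  rownames(dataset$counts) <- dataset$genes$name
  colnames(dataset$counts) <- dataset$lanes$sample_id
  dataset$scale <- scale
  validate_dataset(dataset)
  dataset
}

# Column subset preserving all annotations
subset_lanes <- function(dataset, idx) {
  dataset$lanes <- dataset$lanes[idx, , drop = FALSE]
  rownames(dataset$lanes) <- NULL
  dataset$counts <- dataset$counts[, idx, drop = FALSE]
  dataset
}
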