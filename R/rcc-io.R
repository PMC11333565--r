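#' Read one RCC lane file
#'
#' RCC files are plain text with XML-like tag-delimited sections (header,
#' sample attributes, lane attributes, a code-summary CSV, messages).  The
#' parser is tolerant of dialect variation seen across instrument software
#' versions: section names are matched case-insensitively, trailing commas
#' are stripped, and both "CodeClass" and "Code Class" column headers are
#' accepted.  Sections other than the ones consumed here are preserved in
#' the `"sections"` attribute but otherwise ignored.
#'
#' Positive-control concentrations (fM) are recovered from the conventional
#' probe naming, e.g. `POS_A(128)`.
#'
#' @param path path to an RCC file.
#' @return A list of class `rcc_lane` with elements `lane` (one-row
#'   data.frame of lane attributes), `genes` (data.frame with columns
#'   `name`, `accession`, `code_class`, `known_concentration`, `count`) and
#'   `path`.
#' @export
read_rcc <- function(path) {
  if (!file.exists(path)) stopf("RCC file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  sections <- split_rcc_sections(lines)
  key <- normalize_section_name(names(sections))
  cs_i <- which(key == "code_summary")
  if (length(cs_i) == 0L)
    stopf("no Code_Summary section in RCC file: %s", path)

  lane_attr <- parse_kv_section(sections[[which(key == "lane_attributes")[1]]] %||% character())
  sample_attr <- parse_kv_section(sections[[which(key == "sample_attributes")[1]]] %||% character())

  genes <- parse_code_summary(sections[[cs_i[1]]], path)

  get_attr <- function(tbl, name, coerce = identity, kind = "lane") {
    v <- tbl[[tolower(name)]]
    if (is.null(v) || !nzchar(v)) {
      warnf("RCC %s attribute '%s' missing in %s", kind, name, basename(path))
      return(coerce(NA))
    }
    coerce(v)
  }
  lane <- data.frame(
    lane_id = get_attr(lane_attr, "ID", as.character),
    sample_id = if (!is.null(sample_attr[["id"]]) && nzchar(sample_attr[["id"]]))
      sample_attr[["id"]] else NA_character_,
    fov_count = get_attr(lane_attr, "FovCount", as.numeric),
    fov_counted = get_attr(lane_attr, "FovCounted", as.numeric),
    binding_density = get_attr(lane_attr, "BindingDensity", as.numeric),
    cartridge_id = if (!is.null(lane_attr[["cartridgeid"]]))
      lane_attr[["cartridgeid"]] else NA_character_,
    stringsAsFactors = FALSE
  )
  structure(list(lane = lane, genes = genes, path = path),
            class = "rcc_lane", sections = sections)
}

# Split raw lines into named <Tag>...</Tag> sections
split_rcc_sections <- function(lines) {
  open <- grep("^\\s*<[^/][^>]*>\\s*$", lines)
  close <- grep("^\\s*</[^>]+>\\s*$", lines)
  sections <- list()
  for (i in open) {
    name <- sub("^\\s*<([^>]+)>\\s*$", "\\1", lines[i])
    end <- close[close > i]
    if (length(end) == 0L) next
    end <- end[1]
    body <- if (end > i + 1L) lines[(i + 1L):(end - 1L)] else character()
    sections[[name]] <- body
  }
  sections
}

normalize_section_name <- function(x) {
  gsub("[ _]+", "_", tolower(trimws(x)))
}

# key,value per line; keys lowercased; trailing commas tolerated
parse_kv_section <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln <- sub(",+\\s*$", "", ln)
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 1L) next
    val <- if (length(parts) >= 2L) paste(parts[-1], collapse = ",") else ""
    out[[tolower(trimws(parts[1]))]] <- trimws(val)
  }
  out
}

parse_code_summary <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stopf("empty Code_Summary section in %s", path)
  header <- tolower(gsub("[ ]", "", strsplit(sub(",+\\s*$", "", lines[1]), ",")[[1]]))
  need <- c("codeclass", "name", "accession", "count")
  col <- match(need, header)
  if (any(is.na(col)))
    stopf("Code_Summary in %s lacks column(s): %s", path,
          paste(need[is.na(col)], collapse = ", "))
  rows <- lines[-1]
  n <- length(rows)
  cc <- nm <- acc <- character(n)
  cnt <- numeric(n)
  for (i in seq_len(n)) {
    parts <- trimws(strsplit(sub(",+\\s*$", "", rows[i]), ",")[[1]])
    if (length(parts) < max(col))
      stopf("Code_Summary row %d in %s has too few fields", i, path)
    cc[i] <- parts[col[1]]
    nm[i] <- parts[col[2]]
    acc[i] <- parts[col[3]]
    raw <- parts[col[4]]
    if (!grepl("^[0-9]+$", raw))
      stopf("non-integer count '%s' at Code_Summary row %d in %s", raw, i, path)
    cnt[i] <- as.numeric(raw)
  }
  if (any(!nzchar(nm))) stopf("empty gene name in Code_Summary of %s", path)
  dup <- duplicated(nm)
  if (any(dup)) {
    warnf("duplicate gene name(s) in %s kept first occurrence: %s",
          basename(path), paste(unique(nm[dup]), collapse = ", "))
    cc <- cc[!dup]; acc <- acc[!dup]; cnt <- cnt[!dup]; nm <- nm[!dup]
  }
  cc <- canonical_code_class(cc)
  conc <- rep(NA_real_, length(nm))
  pos <- cc == "Positive"
  conc[pos] <- vapply(nm[pos], function(s) {
    hit <- regmatches(s, regexpr("\\(([0-9.]+)\\)", s))
    if (length(hit) == 1L) as.numeric(gsub("[()]", "", hit)) else NA_real_
  }, numeric(1))
  data.frame(name = nm, accession = acc, code_class = cc,
             known_concentration = conc, count = cnt,
             stringsAsFactors = FALSE)
}

#' Read a sample metadata table
#'
#' A delimited file (comma or tab, autodetected from the header line) with
#' an identifier column (`id`, `sample_id`, `lane_id` or `sample`) and
#' optional `group` and `batch` columns.
#'
#' @param path path to the metadata file.
#' @return data.frame with columns `id`, `group`, `batch`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  md <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(md) <- tolower(names(md))
  idcol <- intersect(c("id", "sample_id", "lane_id", "sample"), names(md))
  if (length(idcol) == 0L)
    stopf("metadata %s needs an id column (id/sample_id/lane_id/sample)", path)
  out <- data.frame(id = as.character(md[[idcol[1]]]), stringsAsFactors = FALSE)
  out$group <- if (!is.null(md$group)) as.character(md$group) else NA_character_
  out$batch <- if (!is.null(md$batch)) as.character(md$batch) else NA_character_
  out
}

#' Assemble parsed RCC lanes into a CountDataset
#'
#' Genes are aligned by name across lanes (row order may differ between
#' files but the panel must be identical), and metadata group/batch labels
#' are joined by sample id, then lane id, then file stem.  Lanes without a
#' metadata row keep `NA` labels.
#'
#' @param lanes list of `rcc_lane` objects from [read_rcc()].
#' @param metadata optional data.frame from [read_metadata()] (or a path).
#' @return A `CountDataset` on the `raw_counts` scale.
#' @export
assemble_dataset <- function(lanes, metadata = NULL) {
  if (length(lanes) < 2L) stopf("need at least 2 lanes, got %d", length(lanes))
  if (is.character(metadata)) metadata <- read_metadata(metadata)

  ref <- lanes[[1]]$genes
  for (i in seq_along(lanes)[-1]) {
    g <- lanes[[i]]$genes
    extra <- setdiff(g$name, ref$name)
    missing <- setdiff(ref$name, g$name)
    if (length(extra) || length(missing))
      stopf("gene panels disagree (lane %d vs lane 1): only-in-lane-%d {%s}; missing {%s}",
            i, i, paste(extra, collapse = ", "), paste(missing, collapse = ", "))
    ord <- match(ref$name, g$name)
    if (any(canonical_code_class(g$code_class[ord]) != canonical_code_class(ref$code_class)))
      stopf("code classes disagree between lane %d and lane 1", i)
  }

  lane_tbl <- do.call(rbind, lapply(lanes, `[[`, "lane"))
  stems <- vapply(lanes, function(l) tools::file_path_sans_ext(basename(l$path %||% "")),
                  character(1))
  # fall back to file stem (then lane id) when the sample attribute is absent
  lane_tbl$sample_id <- ifelse(is.na(lane_tbl$sample_id) | !nzchar(lane_tbl$sample_id),
                               ifelse(nzchar(stems), stems, lane_tbl$lane_id),
                               lane_tbl$sample_id)
  if (anyDuplicated(lane_tbl$lane_id))
    stopf("duplicate lane_id: %s",
          paste(unique(lane_tbl$lane_id[duplicated(lane_tbl$lane_id)]), collapse = ", "))

  counts <- vapply(lanes, function(l) l$genes$count[match(ref$name, l$genes$name)],
                   numeric(nrow(ref)))
  counts <- matrix(counts, nrow = nrow(ref))

  lane_tbl$group <- NA_character_
  lane_tbl$batch <- NA_character_
  if (!is.null(metadata)) {
    for (i in seq_len(nrow(lane_tbl))) {
      hit <- match(lane_tbl$sample_id[i], metadata$id)
      if (is.na(hit)) hit <- match(lane_tbl$lane_id[i], metadata$id)
      if (is.na(hit)) hit <- match(stems[i], metadata$id)
      if (!is.na(hit)) {
        lane_tbl$group[i] <- metadata$group[hit]
        lane_tbl$batch[i] <- metadata$batch[hit]
      }
    }
  }
  rownames(lane_tbl) <- NULL
  count_dataset(ref[c("name", "accession", "code_class", "known_concentration")],
                lane_tbl, counts, scale = "raw_counts")
}

#' Read a directory of RCC files into a CountDataset
#'
#' Files matching `*.rcc`/`*.RCC` are read in sorted name order.
#'
#' @param dir directory containing RCC files.
#' @param metadata optional metadata path or data.frame.
#' @return A `CountDataset`.
#' @export
read_rcc_dir <- function(dir, metadata = NULL) {
  files <- sort(list.files(dir, pattern = "\\.rcc$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) < 2L) stopf("fewer than 2 RCC files in %s", dir)
  assemble_dataset(lapply(files, read_rcc), metadata)
}

#' Write a count matrix to a TSV file
#'
#' First line is a `# scale:` comment recording the scale tag; then a
#' header row (`Gene` + one sample id per lane) and one row per gene.
#' Numbers are written with 15 significant digits so values round-trip.
#'
#' @param dataset a `CountDataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(dataset, path) {
  validate_dataset(dataset)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale: %s", dataset$scale), con)
  writeLines(paste(c("Gene", dataset$lanes$sample_id), collapse = "\t"), con)
  num <- apply(dataset$counts, 2, function(col)
    vapply(col, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE),
           character(1)))
  num <- matrix(num, nrow = nrow(dataset$counts))
  writeLines(paste(dataset$genes$name,
                   apply(num, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path TSV path.
#' @return numeric matrix with the scale tag in attribute `"scale"`.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  scale <- "raw_counts"
  if (startsWith(lines[1], "# scale:")) {
    scale <- trimws(sub("^# scale:", "", lines[1]))
    lines <- lines[-1]
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  m <- t(vapply(body, function(p) as.numeric(p[-1]), numeric(length(header) - 1L)))
  m <- matrix(m, ncol = length(header) - 1L)
  rownames(m) <- vapply(body, `[[`, character(1), 1L)
  colnames(m) <- header[-1]
  attr(m, "scale") <- scale
  m
}
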