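# In-code fixtures shared across the suite.

# Minimal dataset builder: counts is genes x lanes; code_class recycled.
tiny_dataset <- function(counts, code_class = "Endogenous",
                         known_concentration = NULL, names = NULL,
                         group = NULL, batch = NULL, binding_density = 1.05,
                         fov_count = 280, fov_counted = 280,
                         scale = "raw_counts") {
  counts <- as.matrix(counts)
  ng <- nrow(counts); nl <- ncol(counts)
  if (is.null(names)) names <- sprintf("G%02d", seq_len(ng))
  genes <- data.frame(
    name = names, accession = NA_character_,
    code_class = rep_len(code_class, ng),
    known_concentration = known_concentration %||% rep(NA_real_, ng),
    stringsAsFactors = FALSE)
  lanes <- data.frame(
    lane_id = as.character(seq_len(nl)),
    sample_id = sprintf("S%02d", seq_len(nl)),
    fov_count = fov_count, fov_counted = fov_counted,
    binding_density = binding_density, cartridge_id = "FIX",
    group = group %||% rep(NA_character_, nl),
    batch = batch %||% rep(NA_character_, nl),
    stringsAsFactors = FALSE)
  count_dataset(genes, lanes, counts, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a hand-built RCC file; code_rows are raw Code_Summary body lines.
write_fixture_rcc <- function(path, code_rows,
                              lane_id = "1", sample_id = "FIX1",
                              fov_count = "280", fov_counted = "280",
                              binding_density = "1.05",
                              header_line = "CodeClass,Name,Accession,Count",
                              lane_attrs = NULL, section_case = identity) {
  la <- lane_attrs %||% c(sprintf("ID,%s", lane_id),
                          sprintf("FovCount,%s", fov_count),
                          sprintf("FovCounted,%s", fov_counted),
                          "ScannerID,SCAN",
                          sprintf("BindingDensity,%s", binding_density),
                          "CartridgeID,CARTFIX")
  lines <- c(
    sprintf("<%s>", section_case("Header")), "FileVersion,1.7",
    sprintf("</%s>", section_case("Header")),
    sprintf("<%s>", section_case("Sample_Attributes")),
    sprintf("ID,%s", sample_id),
    sprintf("</%s>", section_case("Sample_Attributes")),
    sprintf("<%s>", section_case("Lane_Attributes")), la,
    sprintf("</%s>", section_case("Lane_Attributes")),
    sprintf("<%s>", section_case("Code_Summary")),
    header_line, code_rows,
    sprintf("</%s>", section_case("Code_Summary")),
    "<Messages>", "</Messages>")
  writeLines(lines, path)
  path
}

# A small standard panel as Code_Summary rows, counts supplied per gene.
panel_rows <- function(counts) {
  stopifnot(length(counts) == 8)
  sprintf(c("Positive,POS_A(128),ERCC_00117.1,%d",
            "Positive,POS_B(32),ERCC_00112.1,%d",
            "Positive,POS_C(8),ERCC_00002.1,%d",
            "Negative,NEG_A,ERCC_00096.1,%d",
            "Negative,NEG_B,ERCC_00041.1,%d",
            "Housekeeping,HK_1,NM_0001.1,%d",
            "Endogenous,GENE_X,NM_0002.1,%d",
            "Endogenous,GENE_Y,NM_0003.1,%d"), counts)
}
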