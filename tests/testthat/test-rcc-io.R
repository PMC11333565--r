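test_that("a single code-summary row parses into an annotated gene record", {
  f <- withr::local_tempfile(fileext = ".RCC")
  write_fixture_rcc(f, "Positive,POS_A(128),ERCC_00117.1,10000")
  r <- read_rcc(f)
  expect_equal(r$genes$name, "POS_A(128)")
  expect_equal(r$genes$code_class, "Positive")
  expect_equal(r$genes$known_concentration, 128)
  expect_equal(r$genes$count, 10000)
  expect_equal(r$genes$accession, "ERCC_00117.1")
})

test_that("lane attributes pass through and missing ones warn", {
  f <- withr::local_tempfile(fileext = ".RCC")
  write_fixture_rcc(f, panel_rows(c(8000, 2000, 500, 10, 12, 900, 50, 700)),
                    fov_count = "280", fov_counted = "280")
  r <- read_rcc(f)
  expect_equal(r$lane$fov_count, 280)
  expect_equal(r$lane$fov_counted, 280)
  expect_equal(r$lane$binding_density, 1.05)
  expect_equal(r$lane$sample_id, "FIX1")

  f2 <- withr::local_tempfile(fileext = ".RCC")
  write_fixture_rcc(f2, panel_rows(rep(10, 8)),
                    lane_attrs = c("ID,1", "FovCount,280",
                                   "BindingDensity,0.8"))
  expect_warning(r2 <- read_rcc(f2), "FovCounted")
  expect_true(is.na(r2$lane$fov_counted))
  expect_equal(r2$lane$binding_density, 0.8)
})

test_that("malformed files raise parse errors naming the problem", {
  f <- withr::local_tempfile(fileext = ".RCC")
  write_fixture_rcc(f, c("Positive,POS_A(128),ERCC_00117.1,100",
                         "Endogenous,GENE_X,NM_1.1,12.5",
                         "Endogenous,GENE_Y,NM_2.1,7"))
  expect_error(read_rcc(f), "12\\.5.*row 2")

  f2 <- withr::local_tempfile(fileext = ".RCC")
  writeLines(c("<Header>", "FileVersion,1.7", "</Header>"), f2)
  expect_error(read_rcc(f2), "Code_Summary")
  expect_error(read_rcc(f2), basename(f2), fixed = TRUE)
})

test_that("dialect variation is tolerated: case, spaces, trailing commas", {
  f <- withr::local_tempfile(fileext = ".RCC")
  write_fixture_rcc(f, c("Positive,POS_A(128),ERCC_00117.1,100,",
                         "endogenous,GENE_X,NM_1.1,42,"),
                    header_line = "Code Class,Name,Accession,Count,",
                    section_case = tolower)
  r <- read_rcc(f)
  expect_equal(r$genes$count, c(100, 42))
  expect_equal(r$genes$code_class, c("Positive", "Endogenous"))
})

test_that("duplicate gene names keep the first occurrence with a warning", {
  f <- withr::local_tempfile(fileext = ".RCC")
  write_fixture_rcc(f, c("Endogenous,GENE_X,NM_1.1,5",
                         "Endogenous,GENE_X,NM_1.1,9",
                         "Endogenous,GENE_Y,NM_2.1,7"))
  expect_warning(r <- read_rcc(f), "GENE_X")
  expect_equal(r$genes$count[r$genes$name == "GENE_X"], 5)
})

make_three_lanes <- function(dir, shuffle = FALSE, counts = NULL) {
  base <- panel_rows(c(8000, 2000, 500, 10, 12, 900, 50, 700))
  set_counts_in_rows <- function(cnt)
    mapply(function(r, cval) sub(",[0-9]+$", paste0(",", cval), r),
           base, cnt, USE.NAMES = FALSE)
  files <- character(3)
  for (j in 1:3) {
    rows <- if (is.null(counts)) {
      set_counts_in_rows(j * c(800, 200, 50, 10, 12, 90, 5, 70))
    } else set_counts_in_rows(counts[, j])
    if (shuffle) rows <- rows[sample(length(rows))]
    files[j] <- file.path(dir, sprintf("L%d.RCC", j))
    write_fixture_rcc(files[j], rows, lane_id = as.character(j),
                      sample_id = sprintf("SAMP%d", j))
  }
  files
}

test_that("lanes with shuffled gene order align by name", {
  dir <- withr::local_tempdir()
  set.seed(7)
  counts <- matrix(sample(10:999, 24), 8, 3)
  files <- make_three_lanes(dir, shuffle = TRUE, counts = counts)
  parsed <- lapply(files, read_rcc)
  ds <- assemble_dataset(parsed)
  # dictionary oracle: per-gene lookup in each parsed lane
  for (j in 1:3) {
    lookup <- stats::setNames(parsed[[j]]$genes$count, parsed[[j]]$genes$name)
    expect_equal(unname(ds$counts[, j]), unname(lookup[ds$genes$name]))
  }
  expect_equal(sum(ds$counts), sum(counts))
  expect_equal(ds$scale, "raw_counts")
})

test_that("assembly is permutation-invariant over input lane order", {
  dir <- withr::local_tempdir()
  files <- make_three_lanes(dir)
  parsed <- lapply(files, read_rcc)
  ds1 <- assemble_dataset(parsed)
  ds2 <- assemble_dataset(parsed[c(3, 1, 2)])
  expect_equal(ds2$counts[, c(2, 3, 1)], ds1$counts,
               ignore_attr = TRUE)
  expect_equal(ds2$genes, ds1$genes)
})

test_that("metadata joins on sample id with lane-id and stem fallbacks", {
  dir <- withr::local_tempdir()
  files <- make_three_lanes(dir)
  md <- data.frame(id = c("SAMP1", "SAMP2", "SAMP3"),
                   group = c("A", "A", "B"), batch = c("b1", "b1", "b2"))
  ds <- assemble_dataset(lapply(files, read_rcc), md)
  expect_equal(ds$lanes$group, c("A", "A", "B"))
  expect_equal(ds$lanes$batch, c("b1", "b1", "b2"))
  # unmatched lanes keep NA labels
  md2 <- data.frame(id = "SAMP2", group = "B", batch = NA)
  ds2 <- assemble_dataset(lapply(files, read_rcc), md2)
  expect_equal(ds2$lanes$group, c(NA, "B", NA))
})

test_that("panel disagreement and duplicate lane ids are errors", {
  dir <- withr::local_tempdir()
  f1 <- write_fixture_rcc(file.path(dir, "a.RCC"),
                          c("Endogenous,GENE_X,NM_1.1,5",
                            "Endogenous,GENE_Y,NM_2.1,7"),
                          lane_id = "1", sample_id = "A")
  f2 <- write_fixture_rcc(file.path(dir, "b.RCC"),
                          "Endogenous,GENE_Y,NM_2.1,7",
                          lane_id = "2", sample_id = "B")
  expect_error(assemble_dataset(list(read_rcc(f1), read_rcc(f2))), "GENE_X")
  f3 <- write_fixture_rcc(file.path(dir, "c.RCC"),
                          c("Endogenous,GENE_X,NM_1.1,5",
                            "Endogenous,GENE_Y,NM_2.1,7"),
                          lane_id = "1", sample_id = "C")
  expect_error(assemble_dataset(list(read_rcc(f1), read_rcc(f3))),
               "duplicate lane_id")
  expect_error(assemble_dataset(list(read_rcc(f1))), "at least 2")
})

test_that("matrix write/read round-trips counts and the scale tag", {
  ds <- tiny_dataset(rbind(c(1, 2), c(3, 4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(ds, f)
  lines <- readLines(f)
  expect_length(lines, 4)  # scale comment + header + 2 gene rows
  expect_match(lines[1], "# scale: raw_counts")
  m <- read_matrix(f)
  expect_equal(unname(m), unname(ds$counts), ignore_attr = TRUE)

  lg <- tiny_dataset(matrix(c(-1.25, 0.5, 2.123456789012345, 3), 2),
                     scale = "log2")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(lg, f2)
  m2 <- read_matrix(f2)
  expect_equal(attr(m2, "scale"), "log2")
  expect_equal(unname(m2), unname(lg$counts), tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("non-integer simulated counts round-trip through TSV at full precision", {
  set.seed(11)
  ds <- tiny_dataset(matrix(rlnorm(20, 5, 2), 5, 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(ds, f)
  m <- read_matrix(f)
  expect_equal(unname(m), unname(ds$counts), tolerance = 1e-13,
               ignore_attr = TRUE)
})
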