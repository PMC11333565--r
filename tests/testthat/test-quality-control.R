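pos_dataset <- function(counts_by_lane, conc = c(128, 32, 8, 2, 0.5)) {
  # one positive per ladder point; counts_by_lane is genes x lanes
  tiny_dataset(counts_by_lane, code_class = "Positive",
               known_concentration = conc,
               names = sprintf("POS_%s", LETTERS[seq_along(conc)]))
}

test_that("FOV percentage follows the imaged/attempted ratio", {
  mk <- function(fc, fd) tiny_dataset(matrix(1, 1, 2), fov_count = fc,
                                      fov_counted = fd)$lanes[1, ]
  expect_equal(fov_metric(mk(280, 280)), 100)
  expect_equal(fov_metric(mk(280, 210)), 75)
  expect_equal(fov_metric(mk(280, 0)), 0)
  expect_true(is.na(fov_metric(mk(NA, 10))))
})

test_that("positive-control linearity matches a least-squares oracle", {
  # counts exactly proportional to concentration -> perfect fit
  ds <- pos_dataset(cbind(1e4 * c(128, 32, 8, 2, 0.5)))
  expect_equal(linearity_metric(ds, 1), 1, tolerance = 1e-7)

  # constant counts across the ladder -> no relationship
  ds0 <- pos_dataset(cbind(rep(500, 5)))
  expect_equal(linearity_metric(ds0, 1), 0)

  # worked ladder, checked against closed-form OLS on the log2 pairs
  counts <- c(8000, 2100, 480, 130, 29)
  ds2 <- pos_dataset(cbind(counts))
  x <- log2(c(128, 32, 8, 2, 0.5)); y <- log2(counts + 0.5)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r2_oracle <- sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(linearity_metric(ds2, 1), r2_oracle, tolerance = 1e-12)

  # fewer than 3 usable ladder points -> unavailable
  ds3 <- pos_dataset(cbind(c(100, 30)), conc = c(128, 32))
  expect_true(is.na(linearity_metric(ds3, 1)))
})

test_that("the lowest ladder point is excluded by default but configurable", {
  conc <- c(128, 32, 8, 2, 0.5, 0.125)
  counts <- c(8000, 2000, 500, 125, 70, 60)  # bottom points off-trend
  ds <- pos_dataset(cbind(counts), conc = conc)
  r2_with <- linearity_metric(ds, 1, exclude_conc = NULL)
  r2_without <- linearity_metric(ds, 1)
  expect_false(isTRUE(all.equal(r2_with, r2_without)))
})

test_that("scaling factors equalize per-lane positive geometric means", {
  # one positive gene whose counts are the lane geomeans (100, 200, 400)
  ds <- pos_dataset(matrix(c(100, 200, 400), 1), conc = 128)
  f <- scaling_factor_metric(ds)
  expect_equal(unname(f), c(7/3, 7/6, 7/12), tolerance = 1e-12)

  ds_eq <- pos_dataset(matrix(500, 2, 3), conc = c(128, 32))
  expect_equal(unname(scaling_factor_metric(ds_eq)), rep(1, 3))

  ds_zero <- pos_dataset(matrix(c(0, 0, 100, 200), 2), conc = c(128, 32))
  expect_equal(unname(scaling_factor_metric(ds_zero))[1], Inf)
})

test_that("below-background percentage counts strictly-below endogenous genes", {
  ds <- tiny_dataset(cbind(c(5, 10, 30)))
  bg <- estimate_background(ds, method = "manual", manual_value = 12)
  expect_equal(unname(below_background_metric(ds, bg)), 200 / 3,
               tolerance = 1e-12)
  bg0 <- estimate_background(ds, method = "manual", manual_value = 0)
  expect_equal(unname(below_background_metric(ds, bg0)), 0)
  bg_hi <- estimate_background(ds, method = "manual", manual_value = 1e6)
  expect_equal(unname(below_background_metric(ds, bg_hi)), 100)
})

test_that("a clean simulated run passes QC and threshold edits flip flags", {
  ds <- simulate_dataset(simulation_config(seed = 5))$dataset
  rep1 <- run_qc(ds)
  expect_true(all(rep1$pass))
  expect_length(rep1$suggested_removals, 0)

  # push one lane's binding density out of range
  ds$lanes$binding_density[2] <- 2.5
  rep2 <- run_qc(ds)
  expect_equal(rep2$flags[[2]], "binding_density")
  expect_false(rep2$pass[2])
  expect_equal(rep2$suggested_removals, ds$lanes$lane_id[2])

  # widening the acceptance range clears the flag
  rep3 <- run_qc(ds, qc_thresholds(bd_range = c(0.1, 3.0)))
  expect_true(all(rep3$pass))
})

test_that("widening any threshold never adds a flag (monotonicity)", {
  set.seed(21)
  for (i in 1:5) {
    ds <- simulate_dataset(simulation_config(seed = 100 + i,
                                             n_endogenous = 40))$dataset
    ds$lanes$binding_density <- runif(nrow(ds$lanes), 0.05, 2.6)
    tight <- qc_thresholds(fov_min_pct = 90, bd_range = c(0.2, 2),
                           linearity_min_r2 = 0.99,
                           positive_scaling_range = c(0.5, 2),
                           below_bg_max_pct = 50)
    loose <- qc_thresholds(fov_min_pct = 50, bd_range = c(0.01, 3),
                           linearity_min_r2 = 0.5,
                           positive_scaling_range = c(0.1, 10),
                           below_bg_max_pct = 95)
    bg <- estimate_background(ds)
    r_tight <- run_qc(ds, tight, bg)
    r_loose <- run_qc(ds, loose, bg)
    for (j in seq_along(r_tight$flags))
      expect_true(all(r_loose$flags[[j]] %in% r_tight$flags[[j]]))
  }
})

test_that("QC reports are lane-permutation equivariant", {
  ds <- simulate_dataset(simulation_config(seed = 8, n_endogenous = 40))$dataset
  perm <- c(3, 1, 2, 5, 4, 6:12)
  ds_p <- ds
  ds_p$lanes <- ds_p$lanes[perm, ]; rownames(ds_p$lanes) <- NULL
  ds_p$counts <- ds_p$counts[, perm]
  r1 <- run_qc(ds)
  r2 <- run_qc(ds_p)
  expect_equal(r2$metrics$positive_scaling_factor,
               r1$metrics$positive_scaling_factor[perm])
  expect_equal(r2$metrics$pct_below_background,
               r1$metrics$pct_below_background[perm])
  expect_equal(unname(r2$pass), unname(r1$pass[perm]))
})

test_that("QC report serializes to JSON and HTML", {
  ds <- simulate_dataset(simulation_config(seed = 5, n_endogenous = 30))$dataset
  rep1 <- run_qc(ds)
  jf <- withr::local_tempfile(fileext = ".json")
  hf <- withr::local_tempfile(fileext = ".html")
  write_qc_report(rep1, json = jf, html = hf)
  parsed <- jsonlite::read_json(jf)
  expect_length(parsed$lanes, nrow(ds$lanes))
  expect_equal(parsed$lanes[[1]]$fov_pct, 100)
  expect_match(readLines(hf, n = 1), "<!DOCTYPE html>")
})

test_that("drop_lanes removes columns only, enforcing a 2-lane minimum", {
  ds <- tiny_dataset(matrix(1:12, 3, 4))
  d2 <- drop_lanes(ds, "2")
  expect_equal(ncol(d2$counts), 3)
  expect_equal(d2$lanes$lane_id, c("1", "3", "4"))
  expect_equal(d2$genes, ds$genes)
  expect_identical(drop_lanes(ds, character()), ds)
  expect_error(drop_lanes(ds, "9"), "unknown lane")
  expect_error(drop_lanes(ds, c("1", "2", "3")), "fewer than 2")
})
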