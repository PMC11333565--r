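PIPELINE_STAGES <- c("ingest", "qc", "normalize", "evaluate")

#' Pipeline configuration
#'
#' Resolved, serializable settings for a full preprocessing run.  Every
#' field has a default; the two normalization branches are the classic
#' scaling pipeline (technical, background, content in a configurable
#' order) and control-gene factor removal (`ruvg`).
#'
#' @param input_dir directory of RCC files.
#' @param metadata optional metadata file path.
#' @param output_dir run output directory.
#' @param thresholds a `QcThresholds` (or plain list with the same
#'   fields).
#' @param remove_lanes lane ids dropped before normalization.
#' @param bg_method,bg_source,bg_altneg_n,bg_manual_value,bg_correct
#'   background estimation (`mean_plus_2sd`/`mean`/`max`/`geomean`/
#'   `manual`), source (`negatives` or `altneg`), alternative-negative
#'   count, manual constant, and correction mode
#'   (`subtract`/`floor`/`skip`).
#' @param branch `"scaling"` or `"ruvg"`.
#' @param stage_order order of the scaling-branch stages; the default
#'   performs technical normalization before background correction.
#' @param technical `"posgeomean"`, `"regression"` or `"none"`.
#' @param content content statistic (`"refgenes"`, `"total"`, `"topn"`,
#'   `"all_endo"`, `"none"`).
#' @param topn top-n size for `content = "topn"`.
#' @param endo_n,min_mean endogenous screening for the candidate pool.
#' @param refgenes_n number of reference genes selected (default 6).
#' @param de_alpha,de_mode group-driven candidate refinement (`"filter"`,
#'   `"flag"` or `"none"`).
#' @param ruv_k,ruv_controls,ruv_pre_norm RUV branch settings; controls
#'   from `"refgenes"` or `"negatives"`, optional `"median_of_ratios"`
#'   pre-normalization.
#' @param standardize gene-wise standardization as a final step.
#' @param seed integer seed recorded and set for the run.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(input_dir, metadata = NULL, output_dir,
                            thresholds = qc_thresholds(),
                            remove_lanes = character(),
                            bg_method = "mean_plus_2sd",
                            bg_source = c("negatives", "altneg"),
                            bg_altneg_n = 10, bg_manual_value = NULL,
                            bg_correct = c("floor", "subtract", "skip"),
                            branch = c("scaling", "ruvg"),
                            stage_order = c("technical", "background", "content"),
                            technical = c("posgeomean", "regression", "none"),
                            content = c("refgenes", "total", "topn",
                                        "all_endo", "none"),
                            topn = 10, endo_n = 10, min_mean = 200,
                            refgenes_n = 6, de_alpha = 0.05,
                            de_mode = c("filter", "flag", "none"),
                            ruv_k = 1,
                            ruv_controls = c("refgenes", "negatives"),
                            ruv_pre_norm = c("none", "median_of_ratios"),
                            standardize = FALSE, seed = 1) {
  cfg <- list(
    input_dir = input_dir, metadata = metadata, output_dir = output_dir,
    thresholds = unclass(thresholds), remove_lanes = remove_lanes,
    bg_method = bg_method, bg_source = match.arg(bg_source),
    bg_altneg_n = bg_altneg_n, bg_manual_value = bg_manual_value,
    bg_correct = match.arg(bg_correct), branch = match.arg(branch),
    stage_order = stage_order, technical = match.arg(technical),
    content = match.arg(content), topn = topn, endo_n = endo_n,
    min_mean = min_mean, refgenes_n = refgenes_n, de_alpha = de_alpha,
    de_mode = match.arg(de_mode), ruv_k = ruv_k,
    ruv_controls = match.arg(ruv_controls),
    ruv_pre_norm = match.arg(ruv_pre_norm),
    standardize = isTRUE(standardize), seed = seed
  )
  if (!setequal(cfg$stage_order, c("technical", "background", "content")))
    stopf("stage_order must be a permutation of technical/background/content")
  do.call(qc_thresholds, cfg$thresholds)  # validates
  structure(cfg, class = "PipelineConfig")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `overrides` (e.g.
#' parsed command-line flags) take precedence over the file, which takes
#' precedence over the defaults.
#'
#' @param path YAML file.
#' @param overrides named list of overriding values.
#' @return a `PipelineConfig`.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

run_background <- function(cfg, dataset) {
  src <- if (cfg$bg_method == "manual") NULL
         else if (cfg$bg_source == "altneg")
           select_alternative_negatives(dataset, n = cfg$bg_altneg_n)
         else NULL
  estimate_background(dataset, method = cfg$bg_method, source_genes = src,
                      manual_value = cfg$bg_manual_value)
}

load_stage_dataset <- function(dir, matrix_file) {
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  lanes <- utils::read.table(file.path(dir, "lanes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c(lane_id = "character",
                                            sample_id = "character"))
  m <- read_matrix(file.path(dir, matrix_file))
  lanes <- lanes[match(colnames(m), lanes$sample_id), , drop = FALSE]
  count_dataset(genes, lanes, m, scale = attr(m, "scale"))
}

select_references <- function(cfg, dataset) {
  choose_reference_genes(dataset, n = cfg$refgenes_n, endo_n = cfg$endo_n,
                         min_mean = cfg$min_mean, alpha = cfg$de_alpha,
                         de_mode = cfg$de_mode)
}

stage_ingest <- function(cfg, dir) {
  dataset <- read_rcc_dir(cfg$input_dir, cfg$metadata)
  utils::write.table(dataset$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$lanes, file.path(dir, "lanes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_matrix(dataset, file.path(dir, "raw.tsv"))
  c("genes.tsv", "lanes.tsv", "raw.tsv")
}

stage_qc <- function(cfg, dir) {
  dataset <- load_stage_dataset(dir, "raw.tsv")
  bg <- run_background(cfg, dataset)
  report <- run_qc(dataset, do.call(qc_thresholds, cfg$thresholds), bg)
  write_qc_report(report, json = file.path(dir, "qc.json"),
                  html = file.path(dir, "qc.html"))
  c("qc.json", "qc.html")
}

stage_normalize <- function(cfg, dir) {
  dataset <- load_stage_dataset(dir, "raw.tsv")
  dataset <- drop_lanes(dataset, cfg$remove_lanes)
  refinfo <- NULL
  outputs <- character()

  if (cfg$branch == "scaling") {
    for (stage in cfg$stage_order) {
      if (stage == "technical" && cfg$technical == "posgeomean") {
        dataset <- technical_normalize(dataset)$dataset
      } else if (stage == "technical" && cfg$technical == "regression") {
        cal <- regression_calibrate(dataset)
        # back to a count-like scale so later stages compose
        dataset <- set_counts(cal$dataset, pmax(2^cal$dataset$counts, 0),
                              scale = "corrected_counts")
      } else if (stage == "background" && cfg$bg_correct != "skip") {
        bg <- run_background(cfg, dataset)
        dataset <- correct_background(dataset, bg, mode = cfg$bg_correct)
      } else if (stage == "content" && cfg$content != "none") {
        if (cfg$content == "refgenes") {
          refinfo <- select_references(cfg, dataset)
          dataset <- content_normalize(dataset, refinfo$selected)$dataset
        } else {
          dataset <- content_normalize(dataset, statistic = cfg$content,
                                       topn = cfg$topn)$dataset
        }
      }
    }
    if (cfg$standardize) dataset <- standardize(dataset)
  } else {  # ruvg branch
    if (cfg$ruv_pre_norm == "median_of_ratios")
      dataset <- median_of_ratios(dataset)$dataset
    controls <- if (cfg$ruv_controls == "negatives") {
      dataset$genes$name[class_idx(dataset, "Negative")]
    } else {
      refinfo <- select_references(cfg, dataset)
      refinfo$selected
    }
    fit <- ruvg_fit(dataset, controls, cfg$ruv_k)
    dataset <- fit$corrected
    ruv_obj <- list(k = fit$k, control_genes = fit$control_genes,
                    W = apply(fit$W, 2, identity))
    jsonlite::write_json(ruv_obj, file.path(dir, "ruv.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, "ruv.json")
  }

  write_matrix(dataset, file.path(dir, "normalized.tsv"))
  outputs <- c(outputs, "normalized.tsv")
  if (!is.null(refinfo)) {
    obj <- list(
      selected = I(refinfo$selected),
      M = as.list(refinfo$stability$M),
      ranking = I(refinfo$stability$ranking),
      pairwise_variation = as.list(refinfo$stability$pairwise_variation),
      de = if (!is.null(refinfo$de)) refinfo$de else NULL
    )
    jsonlite::write_json(obj, file.path(dir, "refgenes.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, "refgenes.json")
  }
  outputs
}

stage_evaluate <- function(cfg, dir) {
  raw <- load_stage_dataset(dir, "raw.tsv")
  raw <- drop_lanes(raw, cfg$remove_lanes)
  norm <- load_stage_dataset(dir, "normalized.tsv")
  cmp <- compare_normalization(raw, norm, out_dir = file.path(dir, "plots"))
  obj <- list(
    verdict = cmp$verdict,
    raw = list(lane_iqr = as.list(cmp$raw$lane_iqr),
               mean_iqr = cmp$raw$mean_iqr,
               pca_variance_explained = cmp$raw$pca$variance_explained),
    normalized = list(lane_iqr = as.list(cmp$normalized$lane_iqr),
                      mean_iqr = cmp$normalized$mean_iqr,
                      pca_variance_explained = cmp$normalized$pca$variance_explained)
  )
  jsonlite::write_json(obj, file.path(dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  "evaluation.json"
}

stage_runner <- function(stage) {
  switch(stage, ingest = stage_ingest, qc = stage_qc,
         normalize = stage_normalize, evaluate = stage_evaluate)
}

run_stages <- function(cfg, dir, stages, provenance) {
  for (stage in stages) {
    warnings_seen <- character()
    outputs <- withCallingHandlers(
      stage_runner(stage)(cfg, dir),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    digests <- as.list(tools::md5sum(file.path(dir, outputs)))
    names(digests) <- outputs
    provenance$stages <- c(provenance$stages,
                           list(list(stage = stage, outputs = digests,
                                     warnings = I(warnings_seen))))
  }
  provenance
}

write_provenance <- function(provenance, dir) {
  jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Run the full preprocessing pipeline
#'
#' Ingests RCC files, writes the raw matrix and QC report, normalizes via
#' the configured branch, evaluates raw vs normalized, and logs every
#' executed stage with output digests to `provenance.json`.  The run is
#' fully determined by (inputs, configuration, seed).
#'
#' @param config a `PipelineConfig`.
#' @return invisible list with `output_dir`, `verdict` and the provenance.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) stopf("need a PipelineConfig")
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  provenance <- list(config = unclass(config), stages = list())
  provenance <- run_stages(config, dir, PIPELINE_STAGES, provenance)
  write_provenance(provenance, dir)
  eval_json <- jsonlite::read_json(file.path(dir, "evaluation.json"))
  invisible(list(output_dir = dir, verdict = eval_json$verdict,
                 provenance = provenance))
}

#' Re-run the pipeline from a given stage
#'
#' Re-executes the named stage and everything downstream inside an
#' existing run directory, reusing cached upstream outputs after checking
#' their digests against the provenance log (a tampered upstream file
#' aborts the rerun).  `overrides` are merged into the stored
#' configuration; the provenance log is appended, never rewritten.
#'
#' @param run_dir directory of a previous [run_pipeline()] run.
#' @param stage one of `"ingest"`, `"qc"`, `"normalize"`, `"evaluate"`.
#' @param overrides named list of `PipelineConfig` fields to change.
#' @return invisible list as in [run_pipeline()].
#' @export
rerun_stage <- function(run_dir, stage, overrides = list()) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  prov_path <- file.path(run_dir, "provenance.json")
  if (!file.exists(prov_path)) stopf("no provenance.json in %s", run_dir)
  provenance <- jsonlite::read_json(prov_path, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE)
  cfg_vals <- provenance$config
  cfg_vals$output_dir <- run_dir
  cfg_vals$remove_lanes <- as.character(unlist(cfg_vals$remove_lanes))
  cfg_vals$stage_order <- as.character(unlist(cfg_vals$stage_order))
  cfg_vals[names(overrides)] <- overrides
  cfg <- do.call(pipeline_config, cfg_vals)

  target_i <- match(stage, PIPELINE_STAGES)
  upstream <- PIPELINE_STAGES[seq_len(target_i - 1L)]
  expected <- list()  # latest recorded digest per upstream file
  for (entry in provenance$stages) {
    if (!(entry$stage %in% upstream)) next
    for (f in names(entry$outputs)) expected[[f]] <- entry$outputs[[f]]
  }
  for (f in names(expected)) {
    cur <- unname(tools::md5sum(file.path(run_dir, f)))
    if (is.na(cur) || !identical(cur, expected[[f]]))
      stopf("upstream output '%s' changed since it was produced; refusing to reuse it", f)
  }
  set.seed(cfg$seed)
  provenance <- run_stages(cfg, run_dir,
                           PIPELINE_STAGES[target_i:length(PIPELINE_STAGES)],
                           provenance)
  write_provenance(provenance, run_dir)
  eval_json <- jsonlite::read_json(file.path(run_dir, "evaluation.json"))
  invisible(list(output_dir = run_dir, verdict = eval_json$verdict,
                 provenance = provenance))
}
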