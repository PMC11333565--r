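#' Configuration for the synthetic nCounter generator
#'
#' The generator emulates the structure of an nCounter run: a
#' positive-control concentration ladder scaled by a multiplicative lane
#' effect, negative controls as low-count background noise, housekeeping
#' genes following only the lane effect, and endogenous genes carrying
#' optional condition-group and batch shifts on top of the lane effect.
#'
#' Defaults describe a typical experiment on a full-size panel: 12 lanes
#' in 2 balanced groups and 1 batch, 730 endogenous genes (20%
#' differentially expressed at 1 log2 fold change), 10 housekeeping
#' genes, 8 negative controls, the conventional 6-point ladder (128 down
#' to 0.125 fM), a technical lane effect log-normal with SD 0.3 (log2), an
#' RNA-input effect with SD 0.4 (log2) on the mRNA probes only, an
#' additive nonspecific-binding background of 12 counts on every probe,
#' and negative-binomial counts with dispersion 0.05 (mild
#' overdispersion, as real nCounter counts show).
#'
#' @param n_lanes number of lanes.
#' @param n_groups number of condition groups (assigned round-robin unless
#'   `group_assignment` is given).
#' @param group_assignment optional explicit per-lane group labels.
#' @param n_batches number of batches (blocked assignment unless
#'   `batch_assignment` is given).
#' @param batch_assignment optional explicit per-lane batch labels.
#' @param n_endogenous,n_housekeeping,n_negatives panel composition.
#' @param ladder positive-control concentrations (fM).
#' @param lane_effect_sd SD (log2) of the multiplicative lane effect.
#' @param lane_effects optional explicit per-lane multipliers (overrides
#'   `lane_effect_sd`).
#' @param content_effect_sd SD (log2) of the per-lane RNA-input effect.
#'   Input amount varies between samples and multiplies the mRNA probes
#'   (housekeeping and endogenous) but not the synthetic spike-in
#'   controls, so positive-control scaling cannot see it; removing it is
#'   the job of content normalization.
#' @param content_effects optional explicit per-lane input multipliers.
#' @param batch_effect log2 shift added to endogenous genes per batch
#'   step.
#' @param group_effect_lfc log2 fold change of differentially expressed
#'   genes per group step.
#' @param n_de number of differentially expressed endogenous genes
#'   (default: 20% of the endogenous panel).
#' @param background_mean mean negative-control count.
#' @param pos_scale counts per fM for the positive ladder.
#' @param endo_mean_range,hk_mean_range log-uniform range for baseline
#'   means.
#' @param noise `"nb"` (negative binomial), `"poisson"`, or `"none"`
#'   (expected values, exactly).
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + disp * mu^2`).
#' @param binding_density,fov_count,fov_counted lane attributes written to
#'   the simulated RCC files.
#' @param seed integer seed; fully determines the output.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_lanes = 12, n_groups = 2,
                              group_assignment = NULL,
                              n_batches = 1, batch_assignment = NULL,
                              n_endogenous = 730, n_housekeeping = 10,
                              n_negatives = 8,
                              ladder = c(128, 32, 8, 2, 0.5, 0.125),
                              lane_effect_sd = 0.3, lane_effects = NULL,
                              content_effect_sd = 0.4, content_effects = NULL,
                              batch_effect = 0, group_effect_lfc = 1,
                              n_de = NULL, background_mean = 12,
                              pos_scale = 250,
                              endo_mean_range = c(20, 5000),
                              hk_mean_range = c(200, 2000),
                              noise = c("nb", "poisson", "none"),
                              nb_dispersion = 0.05,
                              binding_density = 1.1,
                              fov_count = 280, fov_counted = 280,
                              seed = 1) {
  noise <- match.arg(noise)
  if (is.null(n_de)) n_de <- round(0.2 * n_endogenous)
  cfg <- list(n_lanes = n_lanes, n_groups = n_groups,
              group_assignment = group_assignment,
              n_batches = n_batches, batch_assignment = batch_assignment,
              n_endogenous = n_endogenous, n_housekeeping = n_housekeeping,
              n_negatives = n_negatives, ladder = ladder,
              lane_effect_sd = lane_effect_sd, lane_effects = lane_effects,
              content_effect_sd = content_effect_sd,
              content_effects = content_effects,
              batch_effect = batch_effect, group_effect_lfc = group_effect_lfc,
              n_de = n_de, background_mean = background_mean,
              pos_scale = pos_scale, endo_mean_range = endo_mean_range,
              hk_mean_range = hk_mean_range, noise = noise,
              nb_dispersion = nb_dispersion, binding_density = binding_density,
              fov_count = fov_count, fov_counted = fov_counted,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_lanes < 2) stopf("n_lanes must be >= 2")
    if (n_groups < 1 || n_groups > n_lanes) stopf("invalid n_groups")
    if (n_batches < 1 || n_batches > n_lanes) stopf("invalid n_batches")
    if (n_endogenous < 1 || n_housekeeping < 0 || n_negatives < 0)
      stopf("invalid panel sizes")
    if (n_de < 0 || n_de > n_endogenous) stopf("n_de must be in [0, n_endogenous]")
    if (any(ladder <= 0)) stopf("ladder concentrations must be positive")
    if (lane_effect_sd < 0 || background_mean < 0 || pos_scale <= 0 ||
        nb_dispersion <= 0)
      stopf("invalid simulation parameter")
    if (!is.null(lane_effects) &&
        (length(lane_effects) != n_lanes || any(lane_effects <= 0)))
      stopf("lane_effects must be %d positive multipliers", n_lanes)
    if (content_effect_sd < 0) stopf("content_effect_sd must be >= 0")
    if (!is.null(content_effects) &&
        (length(content_effects) != n_lanes || any(content_effects <= 0)))
      stopf("content_effects must be %d positive multipliers", n_lanes)
    if (!is.null(group_assignment) && length(group_assignment) != n_lanes)
      stopf("group_assignment must have length n_lanes")
    if (!is.null(batch_assignment) && length(batch_assignment) != n_lanes)
      stopf("batch_assignment must have length n_lanes")
    if (!is_scalar_number(seed)) stopf("seed must be a single number")
  })
  invisible(cfg)
}

draw_counts <- function(mu, noise, dispersion) {
  switch(noise,
         none = mu,
         poisson = stats::rpois(length(mu), mu),
         nb = stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion))
}

#' Simulate an annotated count dataset with known ground truth
#'
#' In-memory counterpart of [simulate_rcc()]: generates the full panel
#' under the configured lane, batch and group effects.  With
#' `noise = "none"` counts equal their expected values exactly, which the
#' recovery tests rely on.
#'
#' @param config a `SimulationConfig`.
#' @return list with `dataset` (a `CountDataset`) and `truth` (list:
#'   `lane_effects`, `de_genes`, `baseline_means`, `group`, `batch`).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nl <- config$n_lanes

  group <- config$group_assignment %||%
    paste0("G", rep_len(seq_len(config$n_groups), nl))
  batch <- config$batch_assignment %||%
    paste0("B", rep(seq_len(config$n_batches), each = ceiling(nl / config$n_batches))[seq_len(nl)])
  m <- config$lane_effects %||% 2^stats::rnorm(nl, 0, config$lane_effect_sd)
  r <- config$content_effects %||% 2^stats::rnorm(nl, 0, config$content_effect_sd)

  runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))
  endo_mu <- runif_log(config$n_endogenous, config$endo_mean_range)
  hk_mu <- if (config$n_housekeeping > 0)
    runif_log(config$n_housekeeping, config$hk_mean_range) else numeric()
  de_genes <- if (config$n_de > 0)
    sprintf("ENDO_%03d", seq_len(config$n_de)) else character()

  pos_letters <- LETTERS[seq_along(config$ladder)]
  genes <- data.frame(
    name = c(sprintf("POS_%s(%s)", pos_letters,
                     vapply(config$ladder, format, character(1))),
             if (config$n_negatives > 0) sprintf("NEG_%s", LETTERS[seq_len(config$n_negatives)]),
             if (config$n_housekeeping > 0) sprintf("HK_%02d", seq_len(config$n_housekeeping)),
             sprintf("ENDO_%03d", seq_len(config$n_endogenous))),
    accession = NA_character_,
    code_class = rep(c("Positive", "Negative", "Housekeeping", "Endogenous"),
                     c(length(config$ladder), config$n_negatives,
                       config$n_housekeeping, config$n_endogenous)),
    known_concentration = c(config$ladder,
                            rep(NA_real_, config$n_negatives +
                                  config$n_housekeeping + config$n_endogenous)),
    stringsAsFactors = FALSE
  )

  group_step <- as.integer(factor(group)) - 1L
  batch_step <- as.integer(factor(batch)) - 1L
  counts <- matrix(0, nrow(genes), nl)
  bg <- config$background_mean
  for (j in seq_len(nl)) {
    # nonspecific binding adds the background level to every probe's signal
    mu_pos <- m[j] * config$pos_scale * config$ladder + bg
    mu_neg <- rep(bg, config$n_negatives)
    mu_hk <- m[j] * r[j] * hk_mu + bg
    shift <- rep(batch_step[j] * config$batch_effect, config$n_endogenous)
    if (length(de_genes))
      shift[seq_len(config$n_de)] <- shift[seq_len(config$n_de)] +
        group_step[j] * config$group_effect_lfc
    mu_endo <- m[j] * r[j] * endo_mu * 2^shift + bg
    counts[, j] <- draw_counts(c(mu_pos, mu_neg, mu_hk, mu_endo),
                               config$noise, config$nb_dispersion)
  }

  lanes <- data.frame(
    lane_id = sprintf("%d", seq_len(nl)),
    sample_id = sprintf("SIM_%02d", seq_len(nl)),
    fov_count = config$fov_count, fov_counted = config$fov_counted,
    binding_density = config$binding_density,
    cartridge_id = "SIMCART",
    group = group, batch = batch,
    stringsAsFactors = FALSE
  )
  dataset <- count_dataset(genes, lanes, counts, scale = "raw_counts")
  truth <- list(lane_effects = stats::setNames(m, lanes$sample_id),
                content_effects = stats::setNames(r, lanes$sample_id),
                de_genes = de_genes,
                baseline_means = stats::setNames(endo_mu, sprintf("ENDO_%03d", seq_len(config$n_endogenous))),
                group = group, batch = batch)
  list(dataset = dataset, truth = truth)
}

#' Write a simulated RCC file set with metadata and ground truth
#'
#' Generates the dataset with [simulate_dataset()] and writes one RCC file
#' per lane (counts rounded to integers, as the instrument reports),
#' a `metadata.csv` (id, group, batch), and ground-truth tables
#' (`truth_lane_effects.tsv`, `truth_de_genes.tsv`).  Identical seeds
#' produce byte-identical files.
#'
#' @param config a `SimulationConfig`.
#' @param dir output directory (created if needed).
#' @return invisible list with `rcc_files`, `metadata`, `truth_files`,
#'   `dataset`, `truth`.
#' @export
simulate_rcc <- function(config, dir) {
  sim <- simulate_dataset(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  rcc_files <- character(nrow(ds$lanes))
  for (j in seq_len(nrow(ds$lanes))) {
    path <- file.path(dir, sprintf("%s.RCC", ds$lanes$sample_id[j]))
    write_rcc_lane(ds, j, path)
    rcc_files[j] <- path
  }
  md_path <- file.path(dir, "metadata.csv")
  utils::write.csv(data.frame(id = ds$lanes$sample_id,
                              group = ds$lanes$group,
                              batch = ds$lanes$batch),
                   md_path, row.names = FALSE, quote = FALSE)
  le_path <- file.path(dir, "truth_lane_effects.tsv")
  utils::write.table(data.frame(sample_id = names(sim$truth$lane_effects),
                                lane_effect = unname(sim$truth$lane_effects)),
                     le_path, sep = "\t", row.names = FALSE, quote = FALSE)
  de_path <- file.path(dir, "truth_de_genes.tsv")
  utils::write.table(data.frame(gene = sim$truth$de_genes),
                     de_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(rcc_files = rcc_files, metadata = md_path,
                 truth_files = c(le_path, de_path),
                 dataset = ds, truth = sim$truth))
}

write_rcc_lane <- function(dataset, j, path) {
  lane <- dataset$lanes[j, ]
  cnt <- format(round(dataset$counts[, j]), scientific = FALSE, trim = TRUE)
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>", "",
    "<Sample_Attributes>",
    sprintf("ID,%s", lane$sample_id),
    "Owner,", "Comments,", "Date,20260101", "GeneRLF,SIM_PANEL",
    "SystemAPF,n.a.",
    "</Sample_Attributes>", "",
    "<Lane_Attributes>",
    sprintf("ID,%s", lane$lane_id),
    sprintf("FovCount,%s", format(lane$fov_count, scientific = FALSE)),
    sprintf("FovCounted,%s", format(lane$fov_counted, scientific = FALSE)),
    "ScannerID,SIMSCAN",
    sprintf("StagePosition,%s", lane$lane_id),
    sprintf("BindingDensity,%s", format(lane$binding_density, scientific = FALSE)),
    sprintf("CartridgeID,%s", lane$cartridge_id),
    "</Lane_Attributes>", "",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,%s,%s", dataset$genes$code_class, dataset$genes$name,
            ifelse(is.na(dataset$genes$accession), "NA",
                   dataset$genes$accession), cnt),
    "</Code_Summary>", "",
    "<Messages>", "</Messages>")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a dataset with designated ultra-stable endogenous candidates
#'
#' Builds a fixture for exercising the stability ranking: `n_stable`
#' designated endogenous genes follow the shared lane effect with only
#' tiny gene-level noise, while every housekeeping gene receives extra
#' independent per-lane log2 noise (`hk_noise_sd`), guaranteeing by
#' construction that the designated genes have lower cross-lane log-ratio
#' variance than any housekeeping gene.  `hk_noise_sd` must exceed
#' `stable_noise_sd`, otherwise no stability ordering is guaranteed and
#' the configuration is refused.
#'
#' @param n_lanes lanes.
#' @param n_stable designated stable endogenous genes (at least 3).
#' @param n_housekeeping housekeeping genes (noisy).
#' @param n_endogenous additional endogenous genes (moderate noise).
#' @param hk_noise_sd extra per-lane log2 noise SD for housekeeping genes.
#' @param stable_noise_sd log2 noise SD of the designated genes.
#' @param seed integer seed.
#' @return list with `dataset`, `stable_genes`, `candidates` (a
#'   `CandidateSet` of housekeeping + designated genes).
#' @export
make_stability_fixture <- function(n_lanes = 8, n_stable = 3,
                                   n_housekeeping = 8, n_endogenous = 30,
                                   hk_noise_sd = 0.4, stable_noise_sd = 0.01,
                                   seed = 1) {
  if (n_stable < 3) stopf("need >= 3 designated stable genes")
  if (hk_noise_sd <= stable_noise_sd)
    stopf("hk_noise_sd must exceed stable_noise_sd for the fixture to force a stability ordering")
  cfg <- simulation_config(n_lanes = n_lanes, n_groups = 1,
                           n_endogenous = n_endogenous + n_stable,
                           n_housekeeping = n_housekeeping,
                           n_de = 0, noise = "none", seed = seed)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  set.seed(seed + 1L)
  stable_genes <- sprintf("STAB_%02d", seq_len(n_stable))
  endo_idx <- class_idx(ds, "Endogenous")
  stable_idx <- endo_idx[seq_len(n_stable)]
  ds$genes$name[stable_idx] <- stable_genes
  hk_idx <- class_idx(ds, "Housekeeping")
  other_endo <- setdiff(endo_idx, stable_idx)
  noisy <- function(rows, sd) {
    ds$counts[rows, ] * 2^matrix(stats::rnorm(length(rows) * n_lanes, 0, sd),
                                 length(rows), n_lanes)
  }
  ds$counts[stable_idx, ] <- noisy(stable_idx, stable_noise_sd)
  ds$counts[hk_idx, ] <- noisy(hk_idx, hk_noise_sd)
  ds$counts[other_endo, ] <- noisy(other_endo, hk_noise_sd / 2)
  rownames(ds$counts) <- ds$genes$name
  validate_dataset(ds)
  cands <- candidate_set(c(ds$genes$name[hk_idx], stable_genes),
                         origin = rep(c("housekeeping", "endogenous"),
                                      c(length(hk_idx), n_stable)))
  list(dataset = ds, stable_genes = stable_genes, candidates = cands)
}
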