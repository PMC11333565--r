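#' Build a candidate reference-gene set
#'
#' Candidates carry an origin (`housekeeping` or `endogenous`) and a
#' positive weight used by the weighted stability ranking (weight 1 is
#' neutral; larger weights make a gene harder to eliminate).
#'
#' @param genes candidate gene names (unique).
#' @param origin per-gene origin, `"housekeeping"` or `"endogenous"`
#'   (recycled).
#' @param weights per-gene positive weights (recycled, default 1).
#' @return data.frame of class `CandidateSet` with columns `gene`,
#'   `origin`, `weight`.
#' @export
candidate_set <- function(genes, origin = "housekeeping", weights = 1) {
  if (anyDuplicated(genes)) stopf("duplicate candidate gene names")
  origin <- rep_len(as.character(origin), length(genes))
  weights <- rep_len(as.numeric(weights), length(genes))
  if (any(!is.finite(weights) | weights <= 0))
    stopf("candidate weights must be positive and finite")
  if (!all(origin %in% c("housekeeping", "endogenous")))
    stopf("origin must be 'housekeeping' or 'endogenous'")
  structure(data.frame(gene = genes, origin = origin, weight = weights,
                       stringsAsFactors = FALSE),
            class = c("CandidateSet", "data.frame"))
}

#' Default candidate pool: housekeeping panel plus screened endogenous
#'
#' @param dataset a `CountDataset`.
#' @param endo_n endogenous genes to add from [screen_endogenous()].
#' @param min_mean expression floor for the endogenous screen.
#' @return a `CandidateSet`.
#' @export
default_candidates <- function(dataset, endo_n = 10, min_mean = 200) {
  hk <- dataset$genes$name[class_idx(dataset, "Housekeeping")]
  endo <- if (endo_n > 0) screen_endogenous(dataset, endo_n, min_mean) else character()
  candidate_set(c(hk, endo),
                origin = rep(c("housekeeping", "endogenous"),
                             c(length(hk), length(endo))))
}

as_candidate_set <- function(candidates) {
  if (inherits(candidates, "CandidateSet")) return(candidates)
  candidate_set(as.character(candidates))
}

#' Screen endogenous genes for reference-gene candidates
#'
#' Among endogenous genes whose mean raw count is at least `min_mean`
#' (genes near background make poor references), returns the `n` genes
#' with the lowest coefficient of variation across lanes; ties are broken
#' by gene name.  If fewer than `n` genes qualify, all qualifying genes
#' are returned with a warning.
#'
#' @param dataset a `CountDataset`.
#' @param n number of genes requested.
#' @param min_mean minimum mean count (default 200; reference genes should
#'   sit well above background, where relative counting noise is small).
#' @return character vector of gene names (possibly shorter than `n`).
#' @export
screen_endogenous <- function(dataset, n, min_mean = 200) {
  if (!is_scalar_number(n) || n < 0) stopf("n must be >= 0")
  if (n == 0) return(character())
  idx <- class_idx(dataset, "Endogenous")
  nm <- dataset$genes$name[idx]
  sub <- dataset$counts[idx, , drop = FALSE]
  mu <- rowMeans(sub)
  ok <- mu >= min_mean
  if (sum(ok) < n)
    warnf("only %d endogenous genes have mean >= %g (requested %d)",
          sum(ok), min_mean, n)
  nm <- nm[ok]; sub <- sub[ok, , drop = FALSE]
  cv <- apply(sub, 1, coef_var)
  nm[order_by_value_then_name(cv, nm)][seq_len(min(n, length(nm)))]
}

# log2 expression of candidate genes, zeros floored at 0.5
candidate_log2 <- function(dataset, genes) {
  idx <- match(genes, dataset$genes$name)
  if (anyNA(idx))
    stopf("candidate genes not in dataset: %s",
          paste(genes[is.na(idx)], collapse = ", "))
  m <- dataset$counts[idx, , drop = FALSE]
  if (dataset$scale == "log2") return(m)
  m[m <= 0] <- 0.5
  log2(m)
}

# M values on a log2 submatrix: mean over partners of the sample SD of the
# pairwise log-ratio across lanes
genorm_m_values <- function(lg) {
  m <- nrow(lg)
  V <- matrix(0, m, m)
  for (j in seq_len(m - 1)) {
    for (k in (j + 1):m) {
      V[j, k] <- V[k, j] <- sample_sd(lg[j, ] - lg[k, ])
    }
  }
  stats::setNames(rowSums(V) / (m - 1), rownames(lg))
}

#' Weighted elimination scores for the stability ranking
#'
#' The gene with the highest score `M / w` is eliminated each round; unit
#' weights reduce exactly to the unweighted algorithm, larger weights
#' protect a gene, smaller weights expose it.
#'
#' @param M named stability values.
#' @param weights positive weights, recycled against `M`.
#' @return named elimination scores.
#' @export
genorm_weighting <- function(M, weights = 1) {
  weights <- rep_len(as.numeric(weights), length(M))
  if (any(!is.finite(weights) | weights <= 0))
    stopf("weights must be positive and finite")
  M / weights
}

#' geNORM-style stability ranking of candidate reference genes
#'
#' For candidates j, k the pairwise variation `V_jk` is the sample SD
#' across lanes of `log2(x_j / x_k)`; the stability value `M_j` is the
#' mean of `V_jk` over all partners (lower = more stable).  The candidate
#' with the highest weighted elimination score `M_j / w_j` is removed and
#' M recomputed, until two genes remain.  Ties are broken by eliminating
#' the alphabetically later gene, making the ranking fully deterministic.
#'
#' The pairwise-variation series `V(n, n+1)` is the sample SD across lanes
#' of `log2(NF_n / NF_{n+1})`, where `NF_n` is the per-lane geometric mean
#' of the n most stable genes; a small `V(n, n+1)` indicates that adding
#' the (n+1)-th reference gene changes the normalization factor little.
#'
#' @param dataset a `CountDataset`.
#' @param candidates a `CandidateSet` or character vector (weights 1).
#' @return Object of class `StabilityResult`: `M` (initial full-set
#'   stability values), `elimination_order` (least to most stable),
#'   `ranking` (most stable first), `pairwise_variation` (named
#'   `V2/3`, ..., length `candidates - 2`), `weights`, `candidates`.
#' @export
genorm_rank <- function(dataset, candidates) {
  cand <- as_candidate_set(candidates)
  if (nrow(cand) < 3L) stopf("need >= 3 candidates, got %d", nrow(cand))
  lg <- candidate_log2(dataset, cand$gene)
  rownames(lg) <- cand$gene
  w <- stats::setNames(cand$weight, cand$gene)

  M_full <- genorm_m_values(lg)
  remaining <- cand$gene
  eliminated <- character()
  while (length(remaining) > 2L) {
    M <- genorm_m_values(lg[remaining, , drop = FALSE])
    score <- genorm_weighting(M, w[remaining])
    # highest score out; ties -> alphabetically later gene eliminated
    ord <- order(-score, remaining, method = "radix")
    worst <- remaining[ord][sum(score == max(score))]
    eliminated <- c(eliminated, worst)
    remaining <- setdiff(remaining, worst)
  }
  ranking <- c(sort(remaining, method = "radix"), rev(eliminated))

  m <- length(ranking)
  V <- numeric(max(m - 2L, 0L))
  lanes_geomean <- function(genes) {
    apply(lg[genes, , drop = FALSE], 2, mean)  # mean of log2 = log2 of geomean
  }
  for (n in seq_len(m - 2L) + 1L) {          # n = 2 .. m-1
    nf_n <- lanes_geomean(ranking[seq_len(n)])
    nf_n1 <- lanes_geomean(ranking[seq_len(n + 1L)])
    V[n - 1L] <- sample_sd(nf_n - nf_n1)
  }
  names(V) <- if (m > 2L) sprintf("V%d/%d", 2:(m - 1L), 3:m) else character()

  structure(list(M = M_full, elimination_order = eliminated, ranking = ranking,
                 pairwise_variation = V, weights = w, candidates = cand),
            class = "StabilityResult")
}

#' @export
print.StabilityResult <- function(x, ...) {
  cat(sprintf("StabilityResult: %d candidates\n", length(x$ranking)))
  cat("ranking (most stable first):", paste(x$ranking, collapse = " > "), "\n")
  cat("M:", paste(sprintf("%s=%.4g", names(x$M), x$M), collapse = ", "), "\n")
  if (length(x$pairwise_variation))
    cat("V:", paste(sprintf("%s=%.4g", names(x$pairwise_variation),
                            x$pairwise_variation), collapse = ", "), "\n")
  invisible(x)
}

#' Pick the n most stable reference genes
#'
#' @param stability a `StabilityResult`.
#' @param n number of genes (default 6, the usual panel size; at least 2).
#' @return character vector of gene names, most stable first.
#' @export
select_best_n <- function(stability, n = 6) {
  if (!inherits(stability, "StabilityResult")) stopf("need a StabilityResult")
  if (!is_scalar_number(n) || n < 2) stopf("n must be >= 2")
  if (n > length(stability$ranking))
    stopf("n = %d exceeds the %d candidates", n, length(stability$ranking))
  stability$ranking[seq_len(n)]
}

# Kruskal-Wallis p-value (chi-square approximation with tie correction),
# returning H = 0, p = 1 for a constant vector where the test is undefined
kw_test <- function(values, groups) {
  if (sample_sd(values) == 0) return(list(statistic = 0, p = 1))
  k <- stats::kruskal.test(values, as.factor(groups))
  p <- k$p.value
  if (!is.finite(p)) p <- 1
  list(statistic = unname(k$statistic), p = p)
}

#' Group-driven differential-expression filter for candidates
#'
#' A reference gene must not differ between condition groups.  Each
#' candidate is tested three ways: a Kruskal-Wallis test across all
#' groups; Wilcoxon rank-sum tests for every group pair (minimum p
#' retained; exact p-values when both groups have at most 10 lanes and no
#' ties, normal approximation with continuity correction otherwise); and a
#' reverse sequential feature selection that considers the combined effect
#' of the candidate set: starting from all candidates, the candidate whose
#' removal most reduces the Kruskal-Wallis statistic of the per-lane
#' geometric mean of the remaining set is removed, until that statistic's
#' p-value reaches `alpha` or two candidates remain.  A candidate is
#' flagged when any criterion trips at `alpha`.
#'
#' @param dataset a `CountDataset`.
#' @param candidates a `CandidateSet` or character vector.
#' @param groups per-lane group labels; defaults to the dataset's lane
#'   metadata.
#' @param alpha significance level (default 0.05).
#' @return data.frame of class `DeFilterResult`: `gene`, `kruskal_H`,
#'   `kruskal_p`, `wilcoxon_min_p`, `sfs_eliminated`, `flagged`; attribute
#'   `alpha`.
#' @export
de_filter <- function(dataset, candidates, groups = NULL, alpha = 0.05) {
  cand <- as_candidate_set(candidates)
  if (is.null(groups)) groups <- dataset$lanes$group
  if (all(is.na(groups)))
    stopf("no group labels: provide a metadata file with a 'group' column")
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    stopf("need >= 2 groups with >= 2 lanes each (got: %s)",
          paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))

  lg <- candidate_log2(dataset, cand$gene)
  n <- nrow(cand)
  kH <- kp <- wp <- numeric(n)
  pairs <- utils::combn(names(tab), 2, simplify = FALSE)
  for (i in seq_len(n)) {
    v <- lg[i, ]
    kw <- kw_test(v, groups)
    kH[i] <- kw$statistic; kp[i] <- kw$p
    if (sample_sd(v) == 0) { wp[i] <- 1; next }
    pvals <- vapply(pairs, function(pr) {
      a <- v[groups == pr[1]]; b <- v[groups == pr[2]]
      exact <- length(a) <= 10L && length(b) <= 10L
      suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                          correct = TRUE)$p.value)
    }, numeric(1))
    pvals[!is.finite(pvals)] <- 1
    wp[i] <- min(pvals)
  }

  # reverse sequential feature selection on the combined normalization factor
  set_H_p <- function(genes) {
    gm <- colMeans(lg[genes, , drop = FALSE])  # log2 of per-lane geomean
    kw_test(gm, groups)
  }
  remaining <- cand$gene
  sfs_elim <- character()
  cur <- set_H_p(remaining)
  while (cur$p < alpha && length(remaining) > 2L) {
    trial <- vapply(remaining,
                    function(g) set_H_p(setdiff(remaining, g))$statistic,
                    numeric(1))
    drop_ord <- order(trial, remaining, method = "radix")
    victim <- remaining[drop_ord][1]
    sfs_elim <- c(sfs_elim, victim)
    remaining <- setdiff(remaining, victim)
    cur <- set_H_p(remaining)
  }
  sfs <- cand$gene %in% sfs_elim
  flagged <- kp < alpha | wp < alpha | sfs
  structure(data.frame(gene = cand$gene, kruskal_H = kH, kruskal_p = kp,
                       wilcoxon_min_p = wp, sfs_eliminated = sfs,
                       flagged = flagged, stringsAsFactors = FALSE),
            alpha = alpha, class = c("DeFilterResult", "data.frame"))
}

#' Select reference genes: screen, refine and rank in one call
#'
#' The full reference-gene workflow used by the pipeline.  Candidate work
#' happens on a provisionally normalized copy of the data (total-count
#' scaling): shared lane-level variation such as RNA input otherwise
#' contaminates both the coefficient-of-variation screen and the
#' group-difference tests — with an unlucky draw the input effect
#' correlates with the condition groups and makes genuinely stable genes
#' look differential (and co-regulated differential genes look stable).
#' The stability ranking itself is scale-invariant, and the returned
#' selection is meant to drive [content_normalize()] on the original
#' data.
#'
#' @param dataset a `CountDataset` on a counts scale.
#' @param n number of reference genes to select (default 6).
#' @param endo_n screened endogenous candidates added to the housekeeping
#'   panel.
#' @param min_mean expression floor for the endogenous screen.
#' @param alpha level for the group-difference refinement.
#' @param de_mode `"filter"`, `"flag"` or `"none"` (skip the group tests;
#'   forced when the dataset has no group labels).
#' @param weights optional named weights for [genorm_rank()] candidates.
#' @return list with `selected`, `stability` (a `StabilityResult`), `de`
#'   (a `DeFilterResult` or NULL) and `candidates` (the refined set).
#' @export
choose_reference_genes <- function(dataset, n = 6, endo_n = 10,
                                   min_mean = 200, alpha = 0.05,
                                   de_mode = c("filter", "flag", "none"),
                                   weights = NULL) {
  de_mode <- match.arg(de_mode)
  pre <- content_normalize(dataset, statistic = "total")$dataset
  cand <- default_candidates(pre, endo_n = endo_n, min_mean = min_mean)
  if (!is.null(weights)) {
    hit <- match(cand$gene, names(weights))
    cand$weight[!is.na(hit)] <- weights[hit[!is.na(hit)]]
  }
  de_tbl <- NULL
  if (de_mode != "none" && any(!is.na(dataset$lanes$group))) {
    de_tbl <- de_filter(pre, cand, alpha = alpha)
    refined <- refine_candidates(cand, de_tbl,
                                 mode = if (de_mode == "flag") "flag" else "filter")
    if (nrow(refined) < 3L) {
      # the ranking needs >= 3 genes: restore the least-offending flagged
      minp <- pmin(de_tbl$kruskal_p, de_tbl$wilcoxon_min_p)
      ord <- cand$gene[order(-minp[match(cand$gene, de_tbl$gene)], cand$gene)]
      extra <- setdiff(ord, refined$gene)
      keep <- c(refined$gene, extra[seq_len(3L - nrow(refined))])
      warnf("filtering left %d candidates; restored to 3 for the ranking",
            nrow(refined))
      refined <- cand[cand$gene %in% keep, , drop = FALSE]
      rownames(refined) <- NULL
      class(refined) <- c("CandidateSet", "data.frame")
    }
    cand <- refined
  }
  stab <- genorm_rank(pre, cand)
  list(selected = select_best_n(stab, min(n, length(stab$ranking))),
       stability = stab, de = de_tbl, candidates = cand)
}

#' Apply the differential-expression filter to a candidate set
#'
#' `filter` mode removes flagged candidates; if fewer than two would
#' remain, the least-offending flagged candidates (largest minimum
#' p-value) are restored with a warning.  `flag` mode keeps every
#' candidate and attaches the per-gene annotation.
#'
#' @param candidates a `CandidateSet`.
#' @param de a `DeFilterResult` for the same genes.
#' @param mode `"filter"` or `"flag"`.
#' @return a `CandidateSet`; in flag mode with a `flagged` column and the
#'   test table in attribute `"de"`.
#' @export
refine_candidates <- function(candidates, de, mode = c("filter", "flag")) {
  mode <- match.arg(mode)
  cand <- as_candidate_set(candidates)
  de_row <- match(cand$gene, de$gene)
  if (anyNA(de_row)) stopf("DE results missing for: %s",
                           paste(cand$gene[is.na(de_row)], collapse = ", "))
  flagged <- de$flagged[de_row]
  if (mode == "flag") {
    cand$flagged <- flagged
    attr(cand, "de") <- de
    return(cand)
  }
  keep <- !flagged
  if (sum(keep) < 2L) {
    minp <- pmin(de$kruskal_p[de_row], de$wilcoxon_min_p[de_row])
    restore <- order(-minp, cand$gene, method = "radix")
    keep[restore[seq_len(2L)]] <- TRUE
    warnf("fewer than 2 candidates unflagged; restored the %d least-offending",
          sum(keep & flagged))
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("CandidateSet", "data.frame")
  out
}
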