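abc_dataset <- function() {
  tiny_dataset(rbind(c(1, 2, 4), c(2, 4, 8), c(1, 1, 1)),
               names = c("A", "B", "C"))
}

test_that("endogenous screening returns the lowest-CV expressed genes", {
  set.seed(2)
  stable <- matrix(rep(c(1000, 1010, 990, 1005), 3), 3, 4, byrow = TRUE)
  noisy <- matrix(rpois(20, 400) * rep(c(1, 3, 1, 2), each = 5), 5, 4)
  ds <- tiny_dataset(rbind(stable, noisy),
                     names = c(sprintf("ST_%d", 1:3), sprintf("NZ_%d", 1:5)))
  expect_setequal(screen_endogenous(ds, 3, min_mean = 50),
                  c("ST_1", "ST_2", "ST_3"))
  # exhaustive CV-sort oracle
  cv <- apply(ds$counts, 1, function(x) sd(x) / mean(x))
  oracle <- ds$genes$name[order(cv, ds$genes$name)][1:3]
  expect_equal(sort(screen_endogenous(ds, 3, min_mean = 50)), sort(oracle))

  expect_equal(screen_endogenous(ds, 0), character())
  # a constant gene has CV zero and is always picked first
  ds2 <- tiny_dataset(rbind(c(500, 500, 500, 500), noisy),
                      names = c("CONST", sprintf("NZ_%d", 1:5)))
  expect_equal(screen_endogenous(ds2, 1, min_mean = 50), "CONST")
  expect_warning(screen_endogenous(ds, 4, min_mean = 1e6), "mean >=")
})

test_that("the A/B/C fixture reproduces the hand-derived stability values", {
  st <- genorm_rank(abc_dataset(), c("A", "B", "C"))
  # V_AB = 0 (B is exactly 2A), V_AC = V_BC = sd(log2(1,2,4)) = 1
  expect_equal(unname(st$M[c("A", "B", "C")]), c(0.5, 0.5, 1))
  expect_equal(st$elimination_order, "C")
  expect_equal(st$ranking, c("A", "B", "C"))
  expect_length(st$pairwise_variation, 1)
  oracle <- oracle_genorm(log2(abc_dataset()$counts))
  expect_equal(unname(st$pairwise_variation), oracle$pairwise_variation)
})

test_that("an exact scalar multiple of a candidate forms the final pair", {
  # Once only three candidates remain, a pair of exact scalar multiples
  # always survives (their mutual variation is 0).  Forced construction:
  # the two other genes are mutually far more unstable than the pair.
  lanes <- 6
  p <- rep(1000, lanes)
  x <- 1000 * 2^seq(-2, 3, length.out = lanes)
  y <- 1000 * 2^seq(3, -2, length.out = lanes)
  ds <- tiny_dataset(rbind(p, 2.5 * p, x, y),
                     names = c("P1", "P2", "X", "Y"))
  st <- genorm_rank(ds, ds$genes$name)
  expect_setequal(st$ranking[1:2], c("P1", "P2"))

  # On random panels of comparable candidates the copied pair ends up as
  # the final pair essentially always; it is not a theorem, though — a
  # chance cluster of mutually tight genes can outlast it once the M tie
  # between the copies is broken.  Any exception must still match the
  # brute-force elimination exactly.
  set.seed(9)
  wins <- 0
  for (i in 1:50) {
    n <- sample(4:7, 1)
    counts <- matrix(2^rnorm(n * 12, 9, 0.5), n, 12)
    dup <- counts[1, ] * runif(1, 0.5, 4)
    ds2 <- tiny_dataset(rbind(counts, dup),
                        names = c(sprintf("C%02d", seq_len(n)), "DUP"))
    st <- genorm_rank(ds2, ds2$genes$name)
    if (setequal(st$ranking[1:2], c("C01", "DUP"))) {
      wins <- wins + 1
    } else {
      oracle <- oracle_genorm(log2(ds2$counts))
      expect_identical(st$ranking, oracle$ranking)
    }
  }
  expect_gte(wins, 48)
})

test_that("identical candidates all score M = 0 and ties break by name", {
  ds <- tiny_dataset(matrix(64, 4, 5), names = c("D", "B", "A", "C"))
  st <- genorm_rank(ds, ds$genes$name)
  expect_equal(unname(st$M), rep(0, 4))
  # alphabetically later genes are eliminated first
  expect_equal(st$elimination_order, c("D", "C"))
  expect_equal(st$ranking, c("A", "B", "C", "D"))
})

test_that("stability is invariant to per-lane scaling", {
  set.seed(10)
  ds <- random_candidate_dataset(6, 8)
  st1 <- genorm_rank(ds, ds$genes$name)
  ds2 <- ds
  ds2$counts[, 3] <- ds2$counts[, 3] * 37.5
  st2 <- genorm_rank(ds2, ds2$genes$name)
  expect_equal(st2$M, st1$M, tolerance = 1e-12)
  expect_equal(st2$ranking, st1$ranking)
  expect_equal(st2$pairwise_variation, st1$pairwise_variation,
               tolerance = 1e-12)
})

test_that("weights reshape the elimination order as declared", {
  ds <- abc_dataset()
  # unit weights reduce to the unweighted algorithm
  st_w1 <- genorm_rank(ds, candidate_set(c("A", "B", "C"), weights = 1))
  st_plain <- genorm_rank(ds, c("A", "B", "C"))
  expect_equal(st_w1$elimination_order, st_plain$elimination_order)
  # a big weight keeps mediocre C in the final pair
  st_keep <- genorm_rank(ds, candidate_set(c("A", "B", "C"),
                                           weights = c(1, 1, 100)))
  expect_true("C" %in% st_keep$ranking[1:2])
  # a tiny weight expels the otherwise stable A first
  st_kill <- genorm_rank(ds, candidate_set(c("A", "B", "C"),
                                           weights = c(0.01, 1, 1)))
  expect_equal(st_kill$elimination_order[1], "A")
  expect_error(genorm_weighting(c(A = 1), weights = -1), "positive")
  expect_error(genorm_rank(ds, c("A", "B")), ">= 3")
})

test_that("select_best_n reads the head of the stability ranking", {
  st <- genorm_rank(abc_dataset(), c("A", "B", "C"))
  expect_equal(select_best_n(st, 3), c("A", "B", "C"))
  expect_equal(select_best_n(st, 2), c("A", "B"))
  expect_error(select_best_n(st, 1), ">= 2")
  expect_error(select_best_n(st, 4), "exceeds")
})

test_that("a stability fixture forces endogenous genes into the best six", {
  fx <- make_stability_fixture(seed = 4)
  st <- genorm_rank(fx$dataset, fx$candidates)
  best6 <- select_best_n(st, 6)
  expect_true(all(fx$stable_genes %in% best6))
  expect_error(make_stability_fixture(hk_noise_sd = 0.01,
                                      stable_noise_sd = 0.01),
               "must exceed")
})

test_that("designated genes proportional to each other top the ranking", {
  fx <- make_stability_fixture(stable_noise_sd = 1e-9, seed = 6)
  st <- genorm_rank(fx$dataset, fx$candidates)
  expect_setequal(st$ranking[seq_along(fx$stable_genes)], fx$stable_genes)
})

test_that("the Kruskal-Wallis worked example gives H = 7.2", {
  ds <- tiny_dataset(matrix(1:9, 1), names = "CAND")
  de <- de_filter(ds, "CAND", groups = rep(c("a", "b", "c"), each = 3))
  expect_equal(de$kruskal_H, 7.2, tolerance = 1e-12)
  expect_equal(de$kruskal_p, stats::pchisq(7.2, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("a constant candidate is never flagged", {
  ds <- tiny_dataset(rbind(rep(100, 8), rpois(8, 200) + 1),
                     names = c("CONST", "VAR"))
  de <- de_filter(ds, c("CONST", "VAR"),
                  groups = rep(c("a", "b"), each = 4))
  row <- de[de$gene == "CONST", ]
  expect_equal(row$kruskal_p, 1)
  expect_equal(row$wilcoxon_min_p, 1)
  expect_false(row$flagged)
})

test_that("a group-driven candidate is caught by the reverse SFS", {
  set.seed(12)
  groups <- rep(c("a", "b"), each = 6)
  flat <- matrix(2^rnorm(5 * 12, 9, 0.05), 5, 12)
  hot <- 2^(9 + ifelse(groups == "b", 3, 0) + rnorm(12, 0, 0.05))
  ds <- tiny_dataset(rbind(flat, hot),
                     names = c(sprintf("FLAT_%d", 1:5), "HOT"))
  de <- de_filter(ds, ds$genes$name, groups = groups)
  expect_true(de$sfs_eliminated[de$gene == "HOT"])
  expect_true(de$flagged[de$gene == "HOT"])

  # brute-force check of the first SFS removal: of all single removals,
  # dropping HOT minimizes the Kruskal-Wallis H of the set geomean
  lg <- log2(ds$counts)
  H_of <- function(rows) {
    v <- colMeans(lg[rows, , drop = FALSE])
    unname(stats::kruskal.test(v, factor(groups))$statistic)
  }
  all_names <- ds$genes$name
  H_without <- vapply(all_names,
                      function(g) H_of(which(all_names != g)), numeric(1))
  expect_equal(names(which.min(H_without)), "HOT")
})

test_that("refinement filters or flags and keeps at least two candidates", {
  ds <- abc_dataset()
  cand <- candidate_set(c("A", "B", "C"))
  de_none <- data.frame(gene = c("A", "B", "C"), kruskal_H = 0,
                        kruskal_p = c(0.9, 0.8, 0.7),
                        wilcoxon_min_p = c(0.9, 0.8, 0.7),
                        sfs_eliminated = FALSE, flagged = FALSE)
  expect_equal(refine_candidates(cand, de_none, "filter")$gene,
               c("A", "B", "C"))

  de_all <- transform(de_none, kruskal_p = c(0.04, 0.01, 0.02),
                      flagged = TRUE)
  expect_warning(kept <- refine_candidates(cand, de_all, "filter"),
                 "least-offending")
  expect_equal(sort(kept$gene), c("A", "C"))  # the two largest minimum p

  flagged <- refine_candidates(cand, de_all, "flag")
  expect_equal(flagged$gene, c("A", "B", "C"))
  expect_true(all(flagged$flagged))
})

test_that("de_filter requires usable group labels", {
  ds <- abc_dataset()
  expect_error(de_filter(ds, c("A", "B", "C")), "group")
  expect_error(de_filter(ds, c("A", "B", "C"), groups = c("a", "a", "b")),
               ">= 2 groups")
})
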