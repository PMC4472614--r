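# Toy-graph expectations below were frozen from hand computation of the
# two-cell chi-square (cross vs non-cross edges) plus the chi-squared tail.

test_that("cross-link counting follows the one-endpoint-in-each rule", {
  toy <- toy_network()
  expect_equal(count_cross_links(toy, gene_set("x", "g1"), gene_set("y", "g2")), 0L)
  # c-d is internal to the fgs and must not be counted
  expect_equal(count_cross_links(toy, gene_set("x", c("a", "b")),
                                 gene_set("y", c("c", "d"))), 2L)
  # overlapping member c: a-c and c-d each counted once
  expect_equal(count_cross_links(toy, gene_set("x", c("a", "c")),
                                 gene_set("y", c("c", "d"))), 2L)
})

test_that("expected cross-links implement the degree-sum formula", {
  toy <- toy_network()
  a <- gene_set("a", c("a", "b")); f <- gene_set("f", c("c", "d"))
  expect_equal(expected_cross_links(toy, a, f), 4 * 5 / (2 * 5))
  expect_equal(expected_cross_links(toy, a, gene_set("f", c("c", "e"))), 1.6)
  # symmetry and absent members
  expect_equal(expected_cross_links(toy, f, a), expected_cross_links(toy, a, f))
  expect_equal(expected_cross_links(toy, gene_set("z", c("q1", "q2")), f), 0)
  empty <- structure(list(nodes = character(0),
                          edges = matrix(character(0), ncol = 2),
                          degree = integer(0), n_total = 0L),
                     class = "gene_network")
  expect_error(expected_cross_links(empty, a, f), "no edges")
})

test_that("nea_score matches the hand-computed toy chi-square", {
  toy <- toy_network()
  r <- nea_score(toy, gene_set("A", c("a", "b")), gene_set("F", c("c", "e")))
  expect_equal(r$n_observed, 2L)
  expect_equal(r$n_expected, 1.6)
  expect_equal(r$chi2, 0.1470588, tolerance = 1e-6)
  expect_equal(r$z, 0.3834825, tolerance = 1e-6)
  expect_equal(r$p, 0.701362, tolerance = 1e-5)
  # zero deviation forces chi2 = 0, p = 1
  r0 <- nea_score(toy, gene_set("A", c("a", "b")), gene_set("F", c("c", "d")))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
})

test_that("z carries the direction and p is the upper chi-squared tail", {
  net <- synth_network(100, 300, seed = 2)
  set.seed(3)
  for (i in 1:20) {
    A <- sample(net$nodes, 10); F <- sample(setdiff(net$nodes, A), 10)
    r <- nea_score(net, gene_set("a", A), gene_set("f", F))
    expect_equal(sign(r$z), sign(r$n_observed - r$n_expected))
    expect_equal(r$p, pchisq(r$chi2, 1, lower.tail = FALSE), tolerance = 1e-12)
    expect_gte(r$chi2, 0)
  }
})

test_that("single-gene mode is nea_score with a singleton FGS", {
  toy <- toy_network()
  r <- single_gene_nea(toy, "c", gene_set("A", c("a", "b")))
  expect_equal(r$n_observed, 2L)
  expect_equal(r$n_expected, 1.2)
  expect_equal(r$chi2, 0.7017544, tolerance = 1e-6)
  expect_equal(r$z, 0.8377078, tolerance = 1e-6)
  expect_equal(r$p, 0.4021948, tolerance = 1e-6)
  # depletion: e has no link to {a, b}
  expect_lt(single_gene_nea(toy, "e", gene_set("A", c("a", "b")))$z, 0)
  # unknown gene: degree 0, degenerate all-zero record, no exception
  r0 <- single_gene_nea(toy, "zz", gene_set("A", c("a", "b")))
  expect_true(r0$degenerate)
  expect_equal(r0$n_observed, 0L)
  expect_equal(r0$p, 1)
})

test_that("internal connectivity uses the halved within-set expectation", {
  toy <- toy_network()
  r <- internal_connectivity(toy, gene_set("A", c("a", "b", "c")))
  expect_equal(r$n_observed, 3L)
  expect_equal(r$conn_ags, 7L)
  expect_equal(r$n_expected, 49 / 20)
  expect_equal(r$chi2, 0.2420968, tolerance = 1e-6)
  expect_gt(r$z, 0)
  # exhaustive set observes every edge
  expect_equal(internal_connectivity(toy, gene_set("A", toy$nodes))$n_observed,
               toy$n_total)
  # unlinked pair in a sparse graph: depletion or zero
  expect_lte(internal_connectivity(toy, gene_set("A", c("a", "e")))$z, 0)
  expect_error(internal_connectivity(toy, gene_set("A", "a")), "2 members")
})

test_that("overlap GSEA reports shared members and the binomial tail", {
  a10 <- gene_set("a", paste0("g", 1:10))
  f50 <- gene_set("f", paste0("g", c(7:10, 100:145)))
  ov <- overlap_gsea(a10, f50, universe_size = 1000)
  expect_equal(ov$shared_members, 4L)
  # closed-form upper binomial tail at >= 4 of 10 draws, hit rate 0.05
  expect_equal(ov$overlap_p, sum(dbinom(4:10, 10, 0.05)), tolerance = 1e-12)
  disjoint <- overlap_gsea(gene_set("a", "x1"), gene_set("f", "x2"), 10)
  expect_equal(disjoint$shared_members, 0L)
  expect_equal(disjoint$overlap_p, 1)
  # ags inside fgs = universe
  all_in <- overlap_gsea(gene_set("a", paste0("g", 1:3)),
                         gene_set("f", paste0("g", 1:8)), 8)
  expect_equal(all_in$shared_members, 3L)
  expect_equal(all_in$overlap_p, 1)
  expect_error(overlap_gsea(a10, f50, universe_size = 10), "universe")
})

test_that("batch NEA applies BH and the minimum-links rule", {
  net <- synth_network(200, 800, seed = 6)
  set.seed(7)
  ags <- lapply(1:3, function(i) gene_set(paste0("a", i), sample(net$nodes, 15)))
  fgs <- lapply(1:5, function(i) gene_set(paste0("f", i), sample(net$nodes, 15)))
  res <- nea_batch(net, ags, fgs, min_links = 5, fdr_threshold = 0.1)
  expect_equal(nrow(res), 15L)
  expect_true(all(res$fdr >= res$p))
  expect_equal(res$fdr, p.adjust(res$p, "BH"))
  expect_equal(res$significant, res$fdr < 0.1 & res$n_observed >= 5)
  # well-supported pair vs under-supported pair at the same tiny fdr
  expect_false(any(res$significant[res$n_observed < 5]))
  # single pair: BH with m = 1 is the identity
  one <- nea_batch(net, ags[[1]], fgs[[1]])
  expect_equal(one$fdr, one$p)
  expect_error(nea_batch(net, list(), fgs), "at least one")
})

test_that("degree-matched random sets preserve size, seed and degree profile", {
  net <- synth_network(500, 2000, seed = 8)
  set.seed(9)
  template <- gene_set("t", sample(net$nodes, 30))
  s1 <- matched_random_sets(net, template, k = 5, seed = 11)
  s2 <- matched_random_sets(net, template, k = 5, seed = 11)
  expect_equal(lapply(s1, `[[`, "members"), lapply(s2, `[[`, "members"))
  expect_true(all(vapply(s1, function(s) length(s$members), 0L) == 30L))
  # stratification keeps the mean degree close over many draws
  many <- matched_random_sets(net, template, k = 100, seed = 13)
  mean_deg <- function(m) mean(net$degree[m])
  ratio <- mean(vapply(many, function(s) mean_deg(s$members), 0)) /
    mean_deg(template$members)
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
})

test_that("edge-swap randomization is deterministic and exact on closed sets", {
  net <- synth_network(100, 300, seed = 14)
  all_nodes <- gene_set("all", net$nodes)
  # every rewired replicate keeps all edges inside the full node set
  r <- randomization_pvalue(net, all_nodes, all_nodes, n_replicates = 20,
                            seed = 15)
  expect_equal(r$p, 1)
  expect_equal(r$null_mean, net$n_total)
  set.seed(16)
  A <- gene_set("a", sample(net$nodes, 12))
  F <- gene_set("f", sample(setdiff(net$nodes, A$members), 12))
  r1 <- randomization_pvalue(net, A, F, n_replicates = 50, seed = 17)
  r2 <- randomization_pvalue(net, A, F, n_replicates = 50, seed = 17)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$z, r2$z)
  tiny <- gene_network(rbind(c("a", "b")))
  expect_error(ms_null_counts(tiny, A, F), "too small")
})
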