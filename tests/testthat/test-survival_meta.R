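test_that("the vectorized score test matches coxph on tie-free data", {
  skip_if_not_installed("survival")
  ss <- synth_survival(n_cohorts = 1, n_patients = 80, n_genes = 40,
                       n_prognostic = 10, hazard_ratio = 2, seed = 91)
  co <- ss$cohorts[[1]]
  mine <- gene_survival_pvalues(co)
  for (g in seq_len(nrow(co$expression))) {
    x <- as.numeric(scale(co$expression[g, ]))
    ref <- survival::coxph(survival::Surv(co$time, co$event) ~ x)
    expect_equal(mine$chi2[g], unname(summary(ref)$sctest["test"]),
                 tolerance = 1e-8)
    expect_equal(mine$direction[g], unname(sign(ref$coefficients)))
  }
})

test_that("score test is null-calibrated and powered as expected", {
  nullsim <- synth_survival(n_cohorts = 1, n_patients = 200, n_genes = 500,
                            n_prognostic = 0, hazard_ratio = 1, seed = 92)
  p0 <- gene_survival_pvalues(nullsim$cohorts[[1]])$p
  expect_gte(mean(p0 < 0.05), 0.03)
  expect_lte(mean(p0 < 0.05), 0.07)
  # hazard ratio 2 per sd at n = 200: detected in >= 80% of seeds
  hits <- vapply(1:20, function(s) {
    ss <- synth_survival(n_cohorts = 1, n_patients = 200, n_genes = 20,
                         n_prognostic = 5, hazard_ratio = 2, seed = 200 + s)
    pv <- gene_survival_pvalues(ss$cohorts[[1]])
    mean(pv$p[pv$gene %in% ss$prognostic] < 0.05)
  }, 0)
  expect_gte(mean(hits), 0.8)
})

test_that("degenerate cohorts are rejected, constant genes get NA", {
  ss <- synth_survival(n_cohorts = 1, n_patients = 30, n_genes = 10,
                       n_prognostic = 0, seed = 93)
  co <- ss$cohorts[[1]]
  co_censored <- cohort_survival("c", co$expression, co$time,
                                 rep(0L, length(co$event)))
  expect_error(gene_survival_pvalues(co_censored), "no events")
  x <- co$expression; x[1, ] <- 7
  co2 <- cohort_survival("c", x, co$time, co$event)
  expect_true(is.na(gene_survival_pvalues(co2)$p[1]))
})

test_that("Fisher combination: identity, frozen pair value, monotone in k", {
  expect_equal(combine_pvalues(0.05), 0.05, tolerance = 1e-12)
  expect_equal(combine_pvalues(c(1, 1)), 1)
  # frozen closed form: X = -2(ln .05 + ln .05) ~ 11.98, 4 df
  expect_equal(combine_pvalues(c(0.05, 0.05)), 0.01747866, tolerance = 1e-7)
  expect_warning(pz <- combine_pvalues(c(0.5, 0)), "clipped")
  expect_gt(pz, 0)
  # combining k copies of the same informative p grows more significant
  ks <- vapply(1:5, function(k) combine_pvalues(rep(0.01, k)), 0)
  expect_true(all(diff(ks) < 0))
})

test_that("Fisher combination of uniform p-values is itself uniform", {
  set.seed(94)
  P <- matrix(runif(10000 * 24), ncol = 24)
  comb <- apply(P[1:50, ], 1, combine_pvalues)   # spot-check the vector path
  X <- -2 * rowSums(log(P))
  comb_all <- pchisq(X, df = 48, lower.tail = FALSE)
  expect_equal(comb, comb_all[1:50], tolerance = 1e-12)
  expect_gt(ks.test(comb_all, "punif")$p.value, 0.01)
})

test_that("multi-cohort associations assemble per-gene combined p-values", {
  ss <- synth_survival(n_cohorts = 4, n_patients = 60, n_genes = 100,
                       n_prognostic = 20, hazard_ratio = 2, seed = 95)
  assoc <- survival_associations(ss$cohorts)
  expect_equal(nrow(assoc), 100L)
  expect_true(all(assoc$combined_p > 0 & assoc$combined_p <= 1))
  expect_true(all(assoc$adjusted_combined_p >= assoc$combined_p))
  expect_equal(ncol(attr(assoc, "directions")), 4L)
  # prognostic genes dominate the ranking
  top20 <- assoc$gene[order(assoc$combined_p)][1:20]
  expect_gte(mean(top20 %in% ss$prognostic), 0.8)
})

test_that("fold enrichment arithmetic and hypergeometric tail are exact", {
  assoc <- data.frame(gene = sprintf("g%04d", 1:1000),
                      combined_p = c(rep(1e-9, 100), rep(0.5, 900)))
  universe <- gene_set("u", assoc$gene)
  cand <- gene_set("cand", c(assoc$gene[1:20], assoc$gene[101:130]))
  rep <- survival_fold_enrichment(cand, assoc, p_cutoff = 1e-6, universe)
  expect_equal(rep$n_list_survival, 20L)
  expect_equal(rep$fold, (20 / 50) / (100 / 1000))  # = 4.0
  expect_equal(rep$p, phyper(19, 100, 900, 50, lower.tail = FALSE),
               tolerance = 1e-12)
  # random lists are unenriched on average
  set.seed(96)
  folds <- replicate(200, {
    cl <- gene_set("r", sample(assoc$gene, 50))
    survival_fold_enrichment(cl, assoc, 1e-6, universe)$fold
  })
  expect_equal(mean(folds), 1, tolerance = 0.1)
  # empty survival set is flagged, not an error
  expect_warning(
    r0 <- survival_fold_enrichment(cand, assoc, p_cutoff = 1e-12, universe),
    "empty survival set")
  expect_true(r0$flagged)
  expect_true(is.na(r0$fold))
  expect_error(survival_fold_enrichment(gene_set("x", "nope"), assoc, 1e-6,
                                        universe), "subset")
})

test_that("neighbor expansion excludes candidates and flags empty lists", {
  net <- gene_network(rbind(c("g1", "g2"), c("g2", "g3"), c("g4", "g5")))
  assoc <- data.frame(gene = paste0("g", 1:8),
                      combined_p = c(rep(1e-9, 4), rep(0.9, 4)))
  universe <- gene_set("u", assoc$gene)
  cand <- gene_set("c", c("g1", "g3"))
  rep <- survival_fold_enrichment(cand, assoc, 1e-6, universe,
                                  expand_neighbors = net)
  expect_equal(rep$n_list, 1L)          # only g2; candidates excluded
  expect_equal(rep$n_list_survival, 1L)
  orphan <- gene_set("o", c("g7", "g8"))
  expect_warning(
    r0 <- survival_fold_enrichment(orphan, assoc, 1e-6, universe,
                                   expand_neighbors = net),
    "no network presence")
  expect_true(r0$flagged)
})
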