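test_that("absent-gene filter uses strict inequalities on both statistics", {
  set.seed(1)
  samples <- tiny_study()$samples
  x <- rbind(
    absent   = rnorm(6, 3.9, sqrt(0.05)),
    expressed = rnorm(6, 10, sqrt(2)),
    boundary_mean = 4.0 + rep(0, 6) + c(-1, 1, -1, 1, -1, 1) * sqrt(0.049 / 2),
    low_mean_high_var = rnorm(6, 3, 2)
  )
  # force the intended mean/variance exactly where the boundary matters
  x["absent", ] <- 3.9 + (x["absent", ] - mean(x["absent", ])) *
    sqrt(0.05 / var(x["absent", ]))
  x["boundary_mean", ] <- 4.0 + (x["boundary_mean", ] - mean(x["boundary_mean", ])) *
    sqrt(0.05 / var(x["boundary_mean", ]))
  colnames(x) <- samples$sample_id
  st <- expression_study(x, samples)
  flt <- filter_absent(st)
  expect_true("ABSENT" %in% flt$removed)
  expect_false("EXPRESSED" %in% flt$removed)
  expect_false("BOUNDARY_MEAN" %in% flt$removed)   # mean == 4 is kept
  expect_false("LOW_MEAN_HIGH_VAR" %in% flt$removed)
  expect_error(filter_absent(st, mean_threshold = -1), "positive")
})

test_that("the filter removes the planted absent cluster and spares signal", {
  sim <- synth_expression(synth_spec(n_genes = 4000, seed = 21))
  flt <- filter_absent(sim$study)
  expect_gte(mean(sim$truth$absent %in% flt$removed), 0.95)
  expressed <- setdiff(rownames(sim$study$matrix), sim$truth$absent)
  expect_lt(mean(expressed %in% flt$removed), 0.01)
})

test_that("paired t-statistics match the closed form and the t.test oracle", {
  # one gene with paired diffs (1, 2, 3, 2) across 4 lines
  ln <- paste0("L", 1:4)
  samples <- data.frame(
    sample_id = c(paste0(ln, "_pre"), paste0(ln, "_post")),
    line_id = rep(ln, 2), condition = rep(c("pre", "post"), each = 4),
    inhibition = "high", origin = "ex_vivo", stringsAsFactors = FALSE)
  pre <- c(5, 5, 5, 5); post <- pre + c(1, 2, 3, 2)
  x <- rbind(G1 = c(pre, post), G2 = c(pre, pre), G3 = rnorm(8, 8))
  colnames(x) <- samples$sample_id
  st <- expression_study(x, samples)
  de <- differential_expression(st, "condition", paired = TRUE)
  expect_equal(de$t_statistic[de$gene == "G1"], 4.898979, tolerance = 1e-6)
  expect_equal(de$p[de$gene == "G1"], 0.0162766, tolerance = 1e-5)
  expect_equal(de$mean_log2_fc[de$gene == "G1"], 2)
  # zero diffs: t = 0, p = 1
  expect_equal(de$t_statistic[de$gene == "G2"], 0)
  expect_equal(de$p[de$gene == "G2"], 1)
  # t.test as independent oracle for the random gene
  ref <- t.test(x["G3", 5:8], x["G3", 1:4], paired = TRUE)
  expect_equal(de$t_statistic[de$gene == "G3"], unname(ref$statistic),
               tolerance = 1e-9)
  expect_equal(de$p[de$gene == "G3"], ref$p.value, tolerance = 1e-9)
})

test_that("independent tests use Welch df and match the t.test oracle", {
  sim <- synth_expression(synth_spec(n_genes = 300, n_confrontation_degs = 20,
                                    n_inhibition_degs = 20, seed = 5))
  flt <- filter_absent(sim$study)
  sub <- subset_samples(flt$study, flt$study$samples$condition == "pre")
  de <- differential_expression(sub, "inhibition", paired = FALSE)
  hi <- sub$samples$inhibition == "high"
  for (g in sample(de$gene, 5)) {
    ref <- t.test(sub$matrix[g, hi], sub$matrix[g, !hi])
    expect_equal(de$t_statistic[de$gene == g], unname(ref$statistic),
                 tolerance = 1e-9)
    expect_equal(de$p[de$gene == g], ref$p.value, tolerance = 1e-9)
    expect_equal(de$df[de$gene == g], unname(ref$parameter), tolerance = 1e-9)
  }
})

test_that("BH adjustment is monotone with q >= p (step-up by hand)", {
  # frozen hand computation: (.01,.02,.03) -> (.03,.03,.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  sim <- synth_expression(synth_spec(n_genes = 1000, n_confrontation_degs = 100,
                                     n_inhibition_degs = 100, seed = 9))
  de <- differential_expression(filter_absent(sim$study)$study, "condition")
  expect_true(all(de$q >= de$p))
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-15))
})

test_that("degenerate zero-variance genes are flagged, not dropped", {
  st <- tiny_study(genes = 3)
  x <- st$matrix
  x[1, ] <- c(1, 1, 1, 2, 2, 2)   # identical diffs: zero within-pair variance
  st <- expression_study(x, st$samples)
  expect_message(de <- differential_expression(st, "condition", paired = TRUE),
                 "zero variance")
  expect_true(de$degenerate[1])
  expect_true(is.infinite(de$t_statistic[1]))
  expect_equal(de$p[1], .Machine$double.xmin)
  expect_equal(nrow(de), 3L)
})

test_that("top DEG ranking is by p with |t| then gene-id tie-breaks", {
  res <- data.frame(gene = c("GB", "GA", "GC", "GD"),
                    t_statistic = c(2, -3, 3, 1),
                    p = c(0.01, 0.01, 0.5, 0.2),
                    q = rep(0.5, 4), mean_log2_fc = 0,
                    stringsAsFactors = FALSE)
  expect_equal(top_degs(res, 2)$members, c("GA", "GB"))  # larger |t| first
  res$t_statistic[1:2] <- c(3, -3)
  expect_equal(top_degs(res, 1)$members, "GA")           # then lexicographic
  expect_equal(length(top_degs(res, 4)$members), 4L)
  expect_error(top_degs(res, 0), "positive")
  expect_error(top_degs(res, 5), "exceeds")
})

test_that("fold changes are per-line post-minus-pre columns", {
  st <- tiny_study()
  fc <- fold_changes(st)
  expect_equal(ncol(fc), 3L)
  expect_equal(unname(fc[, "L1"]),
               unname(st$matrix[, "L1_post"] - st$matrix[, "L1_pre"]))
  # a line with pre == post gives an all-zero column
  x <- st$matrix; x[, "L2_post"] <- x[, "L2_pre"]
  expect_true(all(fold_changes(expression_study(x, st$samples))[, "L2"] == 0))
  expect_error(fold_changes(subset_samples(st, st$samples$sample_id != "L3_post")),
               "L3")
})

test_that("PCA variance fractions are non-increasing and detect rank", {
  set.seed(31)
  m <- matrix(rnorm(500 * 6), ncol = 6)
  fr <- pca_variance_explained(m, 5)
  expect_true(all(diff(fr) <= 1e-12))
  expect_lte(sum(fr), 1 + 1e-12)
  # duplicated identical columns (distinct genes): rank 1, PC1 = 100%
  v <- rnorm(100)
  m1 <- cbind(v, v, 3 * v)   # rank 1 after centering, with duplicate columns
  expect_warning(fr1 <- pca_variance_explained(m1, 3), "truncating")
  expect_equal(fr1[1], 1)
})

test_that("profile correlations behave at the extremes and reject constants", {
  st <- tiny_study(genes = 3)
  x <- st$matrix
  x[2, ] <- 2 * x[1, ] + 3          # perfectly correlated
  x[3, ] <- -x[1, ]                 # perfectly anti-correlated
  st <- expression_study(x, st$samples)
  expect_equal(correlate_pair(st, "g1", "g2")$r, 1, tolerance = 1e-12)
  expect_equal(correlate_pair(st, "g1", "g3")$r, -1, tolerance = 1e-12)
  x[2, ] <- 5
  stc <- expression_study(x, st$samples)
  expect_error(correlate_pair(stc, "g1", "g2"), "constant")
  expect_error(correlate_pair(st, "g1", "nope"), "not in matrix")
})

test_that("cross-model fold-change correlation: identity and null behavior", {
  sim <- synth_expression(synth_spec(n_genes = 3000, seed = 41))
  st <- filter_absent(sim$study)$study
  same <- cross_model_fold_change_correlation(st, c("FL5", "FL1"),
                                              c("FL5", "FL1"), when = "pre")
  expect_equal(same$r, 1)
  # two pairs sharing no lines: per-gene differences are nearly independent
  # (the planted inhibition effect is common, so a weak positive r remains)
  x <- cross_model_fold_change_correlation(st, c("FL5", "FL1"),
                                           c("FL6", "FL2"), when = "pre")
  expect_lt(abs(x$r), 0.25)
  expect_error(cross_model_fold_change_correlation(st, c("FL1", "nope"),
                                                   c("FL6", "FL2")), "nope")
})

test_that("paired and independent tests agree without between-line variance", {
  # no line baseline: same numerator, matching denominators in expectation
  set.seed(51)
  ln <- paste0("L", 1:8)
  samples <- data.frame(
    sample_id = c(paste0(ln, "_pre"), paste0(ln, "_post")),
    line_id = rep(ln, 2), condition = rep(c("pre", "post"), each = 8),
    inhibition = "high", origin = "ex_vivo", stringsAsFactors = FALSE)
  x <- matrix(rnorm(500 * 16, 8, 0.5), nrow = 500,
              dimnames = list(sprintf("g%03d", 1:500), samples$sample_id))
  x[1:50, 9:16] <- x[1:50, 9:16] + 1
  st <- expression_study(x, samples)
  tp <- differential_expression(st, "condition", paired = TRUE)$t_statistic
  ti <- differential_expression(st, "condition", paired = FALSE)$t_statistic
  expect_gt(cor(tp, ti), 0.95)
})
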