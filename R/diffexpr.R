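row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

#' Remove likely-absent genes
#'
#' On log2 microarray intensities, genes that are not expressed form a
#' cluster of low mean and low variance across all samples. A gene is
#' removed iff its variance across all samples is strictly below
#' `var_threshold` *and* its mean is strictly below `mean_threshold`
#' (defaults 0.1 and 4, on the log2 scale). After this filter the
#' mean-variance dependence that would bias the t-tests is gone.
#'
#' @param study An [expression_study] with at least 2 samples.
#' @param mean_threshold,var_threshold Strictly positive thresholds.
#' @return List with `study` (the filtered [expression_study]) and `removed`
#'   (character vector of removed gene ids).
#' @export
filter_absent <- function(study, mean_threshold = 4, var_threshold = 0.1) {
  if (mean_threshold <= 0 || var_threshold <= 0) {
    stop("filter_absent: thresholds must be positive")
  }
  x <- study$matrix
  if (ncol(x) < 2L) stop("filter_absent: need at least 2 samples")
  drop <- row_vars(x) < var_threshold & rowMeans(x) < mean_threshold
  list(study = expression_study(x[!drop, , drop = FALSE], study$samples),
       removed = rownames(x)[drop])
}

contrast_levels <- function(contrast, levels) {
  if (!is.null(levels)) return(levels)
  switch(contrast,
         condition = c("post", "pre"),
         inhibition = c("high", "low"),
         stop("differential_expression: supply `levels` for contrast '",
              contrast, "'"))
}

#' Per-gene differential expression (paired or independent t-tests)
#'
#' Splits the samples into two groups by a sample-sheet column and computes a
#' per-gene t-test: paired by fibroblast line (the self-controlled pre/post
#' design) or independent with the Welch degrees-of-freedom correction.
#' Two-sided p-values are adjusted by Benjamini-Hochberg across all tested
#' genes. A gene with zero within-group variance and a nonzero mean
#' difference gets an infinite t, the smallest representable p, and a
#' degeneracy flag (with a message); the test statistic is undefined there
#' but the gene clearly ranks first.
#'
#' @param study An [expression_study] (typically after [filter_absent]).
#' @param contrast Sample-sheet column defining the two groups
#'   (`"condition"` or `"inhibition"`, or any column when `levels` is given).
#' @param paired Pair samples by `line_id` (requires exactly one sample per
#'   line in each group).
#' @param levels Length-2 character: the group levels, first minus second in
#'   the reported fold change. Defaults: `post - pre` for condition,
#'   `high - low` for inhibition.
#' @return Data frame of class `de_result` with columns `gene`,
#'   `t_statistic`, `df`, `p`, `q`, `mean_log2_fc`, `degenerate`.
#' @export
differential_expression <- function(study, contrast = "condition",
                                    paired = contrast == "condition",
                                    levels = NULL) {
  lv <- contrast_levels(contrast, levels)
  grp <- study$samples[[contrast]]
  if (is.null(grp)) stop("differential_expression: no sample column '", contrast, "'")
  i1 <- which(grp == lv[1]); i2 <- which(grp == lv[2])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("differential_expression: each group needs at least 2 samples")
  }
  x <- study$matrix
  if (paired) {
    l1 <- study$samples$line_id[i1]; l2 <- study$samples$line_id[i2]
    if (anyDuplicated(l1) || anyDuplicated(l2) || !setequal(l1, l2)) {
      stop("differential_expression: paired test needs exactly one '",
           lv[1], "' and one '", lv[2], "' sample per line")
    }
    d <- x[, i1[order(l1)], drop = FALSE] - x[, i2[order(l2)], drop = FALSE]
    n <- ncol(d)
    md <- rowMeans(d)
    sdd <- sqrt(row_vars(d))
    df <- n - 1L
    tstat <- md / (sdd / sqrt(n))
    fc <- md
  } else {
    x1 <- x[, i1, drop = FALSE]; x2 <- x[, i2, drop = FALSE]
    n1 <- ncol(x1); n2 <- ncol(x2)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- row_vars(x1); v2 <- row_vars(x2)
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
    tstat <- (m1 - m2) / sqrt(se2)
    fc <- m1 - m2
  }
  degenerate <- !is.finite(tstat)
  zero_diff <- degenerate & fc == 0
  tstat[zero_diff] <- 0
  degenerate[zero_diff] <- FALSE
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[zero_diff] <- 1
  if (any(degenerate)) {
    message("differential_expression: ", sum(degenerate),
            " gene(s) with zero variance and nonzero difference; p set to minimum")
    tstat[degenerate] <- sign(fc[degenerate]) * Inf
    p[degenerate] <- .Machine$double.xmin
  }
  res <- data.frame(gene = rownames(x), t_statistic = tstat,
                    df = if (length(df) == 1L) rep(df, nrow(x)) else df,
                    p = p, q = stats::p.adjust(p, method = "BH"),
                    mean_log2_fc = fc, degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Top differentially expressed genes as a gene set
#'
#' The `n` genes with smallest p-value; ties broken by larger absolute t,
#' then lexicographic gene id.
#'
#' @param results A `de_result` data frame from [differential_expression].
#' @param n Number of genes (`0 < n <= nrow(results)`).
#' @param id Identifier of the returned set.
#' @return A [gene_set].
#' @export
top_degs <- function(results, n, id = NULL) {
  if (n <= 0L) stop("top_degs: n must be positive")
  if (n > nrow(results)) stop("top_degs: n exceeds the number of tested genes")
  ord <- order(results$p, -abs(results$t_statistic), results$gene)
  gene_set(id %||% paste0("top", n), results$gene[ord[seq_len(n)]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-line fold-change matrix
#'
#' One column per fibroblast line: the post-confrontation minus the
#' pre-confrontation log2 value of each gene.
#'
#' @param study An [expression_study] with paired pre/post samples per line.
#' @return Numeric matrix, genes x lines.
#' @export
fold_changes <- function(study) {
  s <- study$samples
  lines <- unique(s$line_id)
  cols <- lapply(lines, function(l) {
    ipre <- which(s$line_id == l & s$condition == "pre")
    ipost <- which(s$line_id == l & s$condition == "post")
    if (length(ipre) != 1L || length(ipost) != 1L) {
      stop("fold_changes: line '", l, "' lacks a matched pre/post sample pair")
    }
    study$matrix[, ipost] - study$matrix[, ipre]
  })
  out <- do.call(cbind, cols)
  colnames(out) <- lines
  out
}

#' Fractions of variance explained by principal components
#'
#' PCA of the columns of a matrix (e.g. per-line fold-change vectors), with
#' genes as variables, each centered. Fractions are non-increasing and sum
#' to at most 1.
#'
#' @param matrix Numeric matrix (genes x columns), at least 2 columns.
#' @param n_components Number of leading components to report; truncated
#'   with a warning when it exceeds the rank.
#' @return Numeric vector of variance fractions.
#' @export
pca_variance_explained <- function(matrix, n_components = ncol(matrix)) {
  if (ncol(matrix) < 2L) stop("pca_variance_explained: need at least 2 columns")
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  fr <- v / sum(v)
  avail <- sum(v > max(v) * 1e-12)
  if (n_components > avail) {
    warning("pca_variance_explained: only ", avail,
            " non-null components available; truncating")
    n_components <- avail
  }
  fr[seq_len(n_components)]
}

#' Correlation between two gene expression profiles
#'
#' Pearson or Spearman correlation (with two-sided p-value) between the
#' profiles of two genes over all samples in the study.
#'
#' @param study An [expression_study].
#' @param gene_a,gene_b Gene symbols present in the (filtered) matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row data frame with `gene_a`, `gene_b`, `method`, `r`, `p`.
#' @export
correlate_pair <- function(study, gene_a, gene_b,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  gene_a <- normalize_symbols(gene_a); gene_b <- normalize_symbols(gene_b)
  x <- study$matrix
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(x)) stop("correlate_pair: gene '", g, "' not in matrix")
  }
  pa <- x[gene_a, ]; pb <- x[gene_b, ]
  if (stats::sd(pa) == 0 || stats::sd(pb) == 0) {
    stop("correlate_pair: constant expression profile, correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(pa, pb, method = method))
  data.frame(gene_a = gene_a, gene_b = gene_b, method = method,
             r = unname(ct$estimate), p = ct$p.value,
             stringsAsFactors = FALSE)
}

#' Fold-change correlation between two model systems
#'
#' For two pairs of fibroblast lines (each given as `c(low, high)` inhibitory
#' line ids), computes the per-gene log2 difference (low minus high) within
#' each pair at the requested condition, and the Spearman rank correlation
#' across genes between the two difference vectors. Used to compare in vitro
#' and ex vivo models at the level of raw per-gene differences.
#'
#' @param study An [expression_study].
#' @param pair_a,pair_b Length-2 character vectors of line ids, `c(low, high)`.
#' @param when Condition at which to compare (`"pre"` or `"post"`).
#' @return One-row data frame with `pair_a`, `pair_b`, `when`, `method`,
#'   `r`, `p`.
#' @export
cross_model_fold_change_correlation <- function(study, pair_a, pair_b,
                                                when = c("pre", "post")) {
  when <- match.arg(when)
  s <- study$samples
  col_of <- function(line) {
    i <- which(s$line_id == line & s$condition == when)
    if (length(i) != 1L) {
      stop("cross_model_fold_change_correlation: no unique '", when,
           "' sample for line '", line, "'")
    }
    i
  }
  da <- study$matrix[, col_of(pair_a[1])] - study$matrix[, col_of(pair_a[2])]
  db <- study$matrix[, col_of(pair_b[1])] - study$matrix[, col_of(pair_b[2])]
  ct <- suppressWarnings(stats::cor.test(da, db, method = "spearman"))
  data.frame(pair_a = paste(pair_a, collapse = "-"),
             pair_b = paste(pair_b, collapse = "-"),
             when = when, method = "spearman",
             r = unname(ct$estimate), p = ct$p.value,
             stringsAsFactors = FALSE)
}
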