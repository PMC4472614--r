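#' TF-target map as an undirected gene network
#'
#' Binding-site predictions become network edges so that the network
#' enrichment machinery can score transcription factors against DEG lists.
#'
#' @param tf_map A [tf_target_map].
#' @return A [gene_network].
#' @export
tf_map_network <- function(tf_map) {
  gene_network(cbind(tf_map$tf, tf_map$target), quiet = TRUE)
}

#' Transcription-factor enrichment against a DEG list
#'
#' Each TF of the map is scored by single-gene network enrichment against
#' the altered gene set, on the network formed by the TF-target edges.
#' Benjamini-Hochberg adjustment is applied over the TFs of the batch;
#' significance additionally requires at least `min_links` individual
#' TF-to-DEG links.
#'
#' @param tf_map A [tf_target_map].
#' @param ags The altered gene set ([gene_set]).
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param min_links Minimum TF-to-AGS links for significance (default 3).
#' @return Data frame of class `nea_result`, one row per TF, with `fdr` and
#'   `significant` columns.
#' @export
tf_enrichment <- function(tf_map, ags, fdr_threshold = 0.01, min_links = 3L) {
  if (nrow(tf_map) == 0L) stop("tf_enrichment: empty TF map")
  ags <- as_gene_set(ags, "ags")
  net <- tf_map_network(tf_map)
  tfs <- unique(tf_map$tf)
  res <- do.call(rbind, lapply(tfs, function(tf) single_gene_nea(net, tf, ags)))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_threshold & res$n_observed >= min_links
  class(res) <- c("nea_result", "data.frame")
  res
}

pair_correlations <- function(zmat, g1, g2, n) {
  r <- rowSums(zmat[g1, , drop = FALSE] * zmat[g2, , drop = FALSE]) / (n - 1L)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2L) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2L)
  list(r = r, p = p)
}

#' Excess of correlated TF-target pairs over an empirical chance baseline
#'
#' Computes the Pearson correlation (and p-value) of every TF-target pair of
#' the map across all samples, counts pairs passing Benjamini-Hochberg FDR <
#' `corr_fdr`, and compares that count with an empirical baseline: the mean
#' count of FDR-passing correlations among `n_null_draws` sets of randomly
#' drawn gene pairs of the same number (pairs of the map excluded from the
#' null). The baseline is empirical, not the nominal FDR rate, because
#' expression data contain genuinely co-regulated random pairs.
#'
#' @param study An [expression_study] (after [filter_absent]).
#' @param tf_map A [tf_target_map]; pairs with either gene missing from the
#'   matrix are dropped with a warning.
#' @param corr_fdr FDR cutoff for calling a pair correlated (default 0.05).
#' @param n_null_draws Number of random-pair draws for the baseline (at
#'   least 100, else the baseline is too unstable and an error is thrown).
#' @param seed Integer seed.
#' @param targets Optional [gene_set]: restrict the tested pairs to targets
#'   inside this set (e.g. a DEG list).
#' @return An object of class `tf_excess_report`: a list with
#'   `n_pairs_tested`, `n_correlated`, `expected_correlated`, `fold_excess`,
#'   `corr_fdr`, `null_counts`, and the per-pair table `pairs`.
#' @export
correlated_pair_excess <- function(study, tf_map, corr_fdr = 0.05,
                                   n_null_draws = 200L, seed = 1L,
                                   targets = NULL) {
  if (n_null_draws < 100L) {
    stop("correlated_pair_excess: n_null_draws must be at least 100")
  }
  pairs <- as.data.frame(tf_map)
  if (!is.null(targets)) {
    targets <- as_gene_set(targets, "targets")
    pairs <- pairs[pairs$target %in% targets$members, , drop = FALSE]
  }
  genes <- rownames(study$matrix)
  ok <- pairs$tf %in% genes & pairs$target %in% genes
  if (any(!ok)) {
    warning("correlated_pair_excess: dropped ", sum(!ok),
            " pair(s) with genes missing from the matrix")
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("correlated_pair_excess: no testable pairs")
  n <- ncol(study$matrix)
  x <- study$matrix
  cm <- rowMeans(x)
  sd_ <- sqrt(row_vars(x))
  sd_[sd_ == 0] <- NA                     # constant profiles never correlate
  zmat <- (x - cm) / sd_
  count_pass <- function(g1, g2) {
    pr <- pair_correlations(zmat, g1, g2, n)
    q <- stats::p.adjust(pr$p, method = "BH")
    list(n = sum(q < corr_fdr, na.rm = TRUE), r = pr$r, p = pr$p, q = q)
  }
  obs <- count_pass(pairs$tf, pairs$target)
  m <- nrow(pairs)
  set.seed(seed)
  map_keys <- paste(pairs$tf, pairs$target, sep = "\r")
  null_counts <- vapply(seq_len(n_null_draws), function(d) {
    g1 <- sample(genes, m, replace = TRUE)
    g2 <- sample(genes, m, replace = TRUE)
    bad <- g1 == g2 | paste(g1, g2, sep = "\r") %in% map_keys
    while (any(bad)) {
      g1[bad] <- sample(genes, sum(bad), replace = TRUE)
      g2[bad] <- sample(genes, sum(bad), replace = TRUE)
      bad <- g1 == g2 | paste(g1, g2, sep = "\r") %in% map_keys
    }
    count_pass(g1, g2)$n
  }, 0L)
  expected <- mean(null_counts)
  structure(list(
    n_pairs_tested = m,
    n_correlated = obs$n,
    expected_correlated = expected,
    fold_excess = if (expected > 0) obs$n / expected else NA_real_,
    corr_fdr = corr_fdr,
    null_counts = null_counts,
    pairs = data.frame(tf = pairs$tf, target = pairs$target,
                       r = obs$r, p = obs$p, q = obs$q,
                       stringsAsFactors = FALSE)
  ), class = "tf_excess_report")
}

#' @export
print.tf_excess_report <- function(x, ...) {
  cat("tf_excess_report:", x$n_correlated, "of", x$n_pairs_tested,
      "pairs correlated (FDR <", x$corr_fdr, ");",
      sprintf("%.2f expected, fold excess %.2f\n",
              x$expected_correlated, x$fold_excess))
  invisible(x)
}
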