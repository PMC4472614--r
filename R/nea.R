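#' Count cross-links between two gene sets
#'
#' Number of distinct network edges with one endpoint in the first set and
#' the other endpoint in the second set. An edge between two genes that are
#' each members of both sets is counted once; edges internal to only one of
#' the sets are not counted. Genes absent from the network contribute
#' nothing.
#'
#' @param network A [gene_network].
#' @param ags,fgs [gene_set] objects (or character vectors of symbols).
#' @return Integer count.
#' @export
count_cross_links <- function(network, ags, fgs) {
  ags <- as_gene_set(ags, "ags"); fgs <- as_gene_set(fgs, "fgs")
  e <- network$edges
  a1 <- e[, 1] %in% ags$members
  a2 <- e[, 2] %in% ags$members
  f1 <- e[, 1] %in% fgs$members
  f2 <- e[, 2] %in% fgs$members
  sum((a1 & f2) | (a2 & f1))
}

set_connectivity <- function(network, set) {
  idx <- names(network$degree) %in% set$members
  sum(network$degree[idx])
}

#' Expected cross-links under the configuration-model null
#'
#' Returns `N_AGS * N_FGS / (2 * N_total)`, where `N_AGS` and `N_FGS` are the
#' sums of network degrees over the members of each set (genes absent from
#' the network contribute degree 0) and `N_total` is the number of edges in
#' the whole network. Symmetric in its two set arguments.
#'
#' @inheritParams count_cross_links
#' @return Non-negative number.
#' @export
expected_cross_links <- function(network, ags, fgs) {
  if (network$n_total == 0L) stop("expected_cross_links: network has no edges")
  ags <- as_gene_set(ags, "ags"); fgs <- as_gene_set(fgs, "fgs")
  set_connectivity(network, ags) * set_connectivity(network, fgs) /
    (2 * network$n_total)
}

# Core chi-squared machinery shared by the between-set and within-set modes.
# The statistic is a 1-df chi-square over the two-cell classification of all
# edges (cross vs non-cross): "other than n" is n_total - n_observed and its
# expectation n_total - n_expected. Direction is carried by the signed z.
chi2_record <- function(ags_id, fgs_id, n_obs, n_exp, n_total,
                        conn_ags, conn_fgs) {
  degenerate <- FALSE
  if (n_exp <= 0) {
    degenerate <- TRUE
    if (n_obs > 0) {               # infinite enrichment, flagged not thrown
      chi2 <- Inf; z <- Inf; p <- .Machine$double.xmin
    } else {
      chi2 <- 0; z <- 0; p <- 1
    }
  } else {
    n_other <- n_total - n_obs
    n_other_exp <- n_total - n_exp
    chi2 <- (n_obs - n_exp)^2 / n_exp
    if (n_other_exp > 0) {
      chi2 <- chi2 + (n_other - n_other_exp)^2 / n_other_exp
    } else {
      degenerate <- TRUE           # expectation exceeds the edge count
    }
    z <- sign(n_obs - n_exp) * sqrt(chi2)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    if (p == 0) p <- .Machine$double.xmin
  }
  data.frame(ags_id = ags_id, fgs_id = fgs_id,
             n_observed = n_obs, n_expected = n_exp,
             n_other = n_total - n_obs, n_other_expected = n_total - n_exp,
             conn_ags = conn_ags, conn_fgs = conn_fgs,
             chi2 = chi2, z = z, p = p, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Network enrichment score for one AGS-FGS pair
#'
#' Chi-squared network enrichment of the altered gene set (AGS) against the
#' functional gene set (FGS): observed cross-links are compared with the
#' configuration-model expectation via a 1-df chi-square over the cross /
#' non-cross classification of all network edges. The upper chi-squared tail
#' gives the p-value; enrichment versus depletion is carried by the sign of
#' `z`. A pair with zero expectation but observed links is returned as a
#' flagged degenerate record (infinite enrichment) rather than an error, so
#' batch runs never abort.
#'
#' @inheritParams count_cross_links
#' @return One-row data frame with columns `ags_id`, `fgs_id`, `n_observed`,
#'   `n_expected`, `n_other`, `n_other_expected`, `conn_ags`, `conn_fgs`,
#'   `chi2`, `z`, `p`, `degenerate`.
#' @export
nea_score <- function(network, ags, fgs) {
  ags <- as_gene_set(ags, "ags"); fgs <- as_gene_set(fgs, "fgs")
  n_obs <- count_cross_links(network, ags, fgs)
  ca <- set_connectivity(network, ags)
  cf <- set_connectivity(network, fgs)
  n_exp <- ca * cf / (2 * network$n_total)
  chi2_record(ags$id, fgs$id, n_obs, n_exp, network$n_total, ca, cf)
}

#' Single-gene network enrichment
#'
#' The functional set is a single gene; the calculation is otherwise
#' identical to [nea_score]. Useful to rank individual regulators (e.g.
#' transcription factors) against a DEG list. A gene unknown to the network
#' yields an all-zero flagged degenerate record.
#'
#' @param network A [gene_network].
#' @param gene Single gene symbol.
#' @param ags The altered gene set.
#' @return One-row data frame as in [nea_score] (with `fgs_id = gene`).
#' @export
single_gene_nea <- function(network, gene, ags) {
  stopifnot(length(gene) == 1L)
  gene <- normalize_symbols(gene)
  nea_score(network, as_gene_set(ags, "ags"), gene_set(gene, gene))
}

#' Internal connectivity of a gene set
#'
#' Coherence test that a gene set forms a network module: the observed count
#' of edges with both endpoints inside the set is compared with
#' `N_AGS^2 / (4 * N_total)` -- the configuration-model expectation obtained
#' by setting FGS = AGS and halving to avoid double-counting unordered
#' within-set pairs.
#'
#' @param network A [gene_network].
#' @param ags A [gene_set] with at least 2 members.
#' @return One-row data frame as in [nea_score] (with `fgs_id == ags_id`).
#' @export
internal_connectivity <- function(network, ags) {
  ags <- as_gene_set(ags, "ags")
  if (length(ags$members) < 2L) {
    stop("internal_connectivity: set must have at least 2 members")
  }
  e <- network$edges
  n_obs <- sum(e[, 1] %in% ags$members & e[, 2] %in% ags$members)
  ca <- set_connectivity(network, ags)
  n_exp <- ca^2 / (4 * network$n_total)
  chi2_record(ags$id, ags$id, n_obs, n_exp, network$n_total, ca, ca)
}

#' Member-overlap enrichment (binomial GSEA companion)
#'
#' Classical overlap enrichment between the same two gene sets: the number of
#' shared member genes and the upper binomial tail probability of observing
#' at least that many when `|AGS|` draws hit a target of frequency
#' `|FGS| / universe_size`.
#'
#' @inheritParams count_cross_links
#' @param universe_size Size of the gene universe; must be at least
#'   `|AGS union FGS|`.
#' @return List with `shared_members` and `overlap_p`.
#' @export
overlap_gsea <- function(ags, fgs, universe_size) {
  ags <- as_gene_set(ags, "ags"); fgs <- as_gene_set(fgs, "fgs")
  if (universe_size < length(union(ags$members, fgs$members))) {
    stop("overlap_gsea: universe smaller than the union of the sets")
  }
  shared <- length(intersect(ags$members, fgs$members))
  q <- length(fgs$members) / universe_size
  p <- stats::pbinom(shared - 1L, size = length(ags$members), prob = q,
                     lower.tail = FALSE)
  list(shared_members = shared, overlap_p = p)
}

#' Batch network enrichment with FDR and the minimum-links rule
#'
#' Scores every AGS x FGS pair, adjusts p-values by Benjamini-Hochberg over
#' the whole batch, and flags a pair as significant when `fdr <
#' fdr_threshold` *and* it is supported by at least `min_links` observed
#' cross-links. Overlap-GSEA companion statistics (shared members, binomial
#' overlap p) are reported alongside.
#'
#' @param network A [gene_network].
#' @param ags_list,fgs_list A [gene_set] or list of gene sets.
#' @param min_links Minimum observed cross-links for significance.
#' @param fdr_threshold FDR cutoff for significance.
#' @param universe_size Universe for the overlap companion statistic;
#'   defaults to the number of network nodes.
#' @return Data frame of class `nea_result`, one row per pair, with the
#'   columns of [nea_score] plus `shared_members`, `overlap_p`, `fdr` and
#'   `significant`.
#' @export
nea_batch <- function(network, ags_list, fgs_list, min_links = 5L,
                      fdr_threshold = 0.1,
                      universe_size = length(network$nodes)) {
  if (inherits(ags_list, "gene_set")) ags_list <- list(ags_list)
  if (inherits(fgs_list, "gene_set")) fgs_list <- list(fgs_list)
  if (length(ags_list) == 0L || length(fgs_list) == 0L) {
    stop("nea_batch: need at least one AGS and one FGS")
  }
  rows <- vector("list", length(ags_list) * length(fgs_list))
  k <- 0L
  for (ags in ags_list) {
    for (fgs in fgs_list) {
      k <- k + 1L
      r <- nea_score(network, ags, fgs)
      ov <- overlap_gsea(ags, fgs, universe_size = universe_size)
      r$shared_members <- ov$shared_members
      r$overlap_p <- ov$overlap_p
      rows[[k]] <- r
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_threshold & res$n_observed >= min_links
  class(res) <- c("nea_result", "data.frame")
  res
}

#' Degree-matched random gene sets
#'
#' Draws `k` random sets of the same size as the template and matching its
#' network degree profile: network nodes are binned into `n_bins` quantile
#' bins of log-degree and each template member is replaced by a random node
#' from its bin (without replacement within a set). Used as negative
#' controls: enrichment calls for such sets should occur at no more than the
#' nominal rate.
#'
#' @param network A [gene_network].
#' @param template A [gene_set]; members without network degrees are dropped
#'   with a warning.
#' @param k Number of random sets.
#' @param n_bins Number of log-degree quantile bins.
#' @param seed Integer seed (draws are reproducible).
#' @return List of `k` [gene_set] objects.
#' @export
matched_random_sets <- function(network, template, k, n_bins = 10L, seed = 1L) {
  stopifnot(k >= 1L)
  template <- as_gene_set(template, "template")
  set.seed(seed)
  deg <- network$degree
  present <- intersect(template$members, names(deg))
  if (length(present) < length(template$members)) {
    warning("matched_random_sets: ", length(template$members) - length(present),
            " template member(s) absent from the network were dropped")
  }
  if (length(present) == 0L) stop("matched_random_sets: template has no network presence")
  breaks <- unique(stats::quantile(log(deg), probs = seq(0, 1, length.out = n_bins + 1L)))
  bin_of <- cut(log(deg), breaks = breaks, include.lowest = TRUE, labels = FALSE)
  names(bin_of) <- names(deg)
  need <- table(bin_of[present])
  widened <- FALSE
  lapply(seq_len(k), function(i) {
    members <- character(0)
    for (b in names(need)) {
      bi <- as.integer(b)
      cand <- names(deg)[bin_of == bi]
      width <- 0L
      while (length(cand) < need[[b]]) {   # widen into adjacent bins
        width <- width + 1L
        cand <- names(deg)[abs(bin_of - bi) <= width]
        if (!widened) {
          warning("matched_random_sets: bin ", b,
                  " had too few candidates; widened to adjacent bins")
          widened <<- TRUE
        }
      }
      members <- c(members, sample(cand, need[[b]]))
    }
    gene_set(paste0(template$id, "_rand", i), members)
  })
}

as_igraph <- function(network) {
  igraph::graph_from_edgelist(network$edges, directed = FALSE)
}

count_cross_links_edgelist <- function(e, a_members, f_members) {
  a1 <- e[, 1] %in% a_members
  a2 <- e[, 2] %in% a_members
  f1 <- e[, 1] %in% f_members
  f2 <- e[, 2] %in% f_members
  sum((a1 & f2) | (a2 & f1))
}

#' Cross-link counts under the degree-preserving edge-swap null
#'
#' Generates `n_replicates` rewired versions of the network by
#' degree-preserving edge swaps (Maslov-Sneppen randomization, via
#' `igraph::rewire(keeping_degseq())`) and counts the cross-links of every
#' supplied AGS-FGS pair on each replicate. The replicates are shared across
#' pairs, which makes large oracle comparisons affordable.
#'
#' @param network A [gene_network] (at least 2 edges).
#' @param ags_list,fgs_list Parallel lists of [gene_set] objects (pair `i` is
#'   `ags_list[[i]]` vs `fgs_list[[i]]`).
#' @param n_swaps_per_edge Swap attempts per edge and replicate.
#' @param n_replicates Number of rewired replicates.
#' @param seed Integer seed.
#' @return Integer matrix, `length(ags_list)` rows x `n_replicates` columns.
#' @export
ms_null_counts <- function(network, ags_list, fgs_list,
                           n_swaps_per_edge = 10L, n_replicates = 100L,
                           seed = 1L) {
  if (inherits(ags_list, "gene_set")) ags_list <- list(ags_list)
  if (inherits(fgs_list, "gene_set")) fgs_list <- list(fgs_list)
  stopifnot(length(ags_list) == length(fgs_list), length(ags_list) >= 1L)
  if (network$n_total < 2L) stop("ms_null_counts: network too small to swap")
  set.seed(seed)
  g <- as_igraph(network)
  niter <- n_swaps_per_edge * network$n_total
  out <- matrix(0L, nrow = length(ags_list), ncol = n_replicates)
  for (r in seq_len(n_replicates)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
    er <- igraph::as_edgelist(gr, names = TRUE)
    for (i in seq_along(ags_list)) {
      out[i, r] <- count_cross_links_edgelist(er, ags_list[[i]]$members,
                                              fgs_list[[i]]$members)
    }
  }
  out
}

#' Empirical enrichment p-value by network randomization
#'
#' Validation oracle for the chi-squared statistic: the observed cross-link
#' count is compared with its distribution over degree-preserving edge-swap
#' replicates of the network. The empirical enrichment-side p-value is
#' `(1 + #(n_random >= n_observed)) / (1 + n_replicates)`; the z-score is
#' `(n_observed - mean_random) / sd_random`.
#'
#' @inheritParams ms_null_counts
#' @param ags,fgs [gene_set] objects.
#' @return List with `p` (empirical enrichment p), `z`, `n_observed`,
#'   `null_mean`, `null_sd`, `n_replicates`.
#' @export
randomization_pvalue <- function(network, ags, fgs, n_swaps_per_edge = 10L,
                                 n_replicates = 100L, seed = 1L) {
  ags <- as_gene_set(ags, "ags"); fgs <- as_gene_set(fgs, "fgs")
  counts <- ms_null_counts(network, list(ags), list(fgs),
                           n_swaps_per_edge = n_swaps_per_edge,
                           n_replicates = n_replicates, seed = seed)[1, ]
  n_obs <- count_cross_links(network, ags, fgs)
  list(p = (1 + sum(counts >= n_obs)) / (1 + n_replicates),
       z = (n_obs - mean(counts)) / stats::sd(counts),
       n_observed = n_obs, null_mean = mean(counts),
       null_sd = stats::sd(counts), n_replicates = n_replicates)
}

#' One-sided (enrichment) p-value from a signed NEA z
#'
#' Converts the two-sided chi-squared p and signed z of [nea_score] into the
#' enrichment-side p-value, comparable with the empirical randomization p.
#'
#' @param p Two-sided chi-squared p-values.
#' @param z Signed z-scores.
#' @return Enrichment-side p-values.
#' @export
nea_one_sided_p <- function(p, z) {
  ifelse(z > 0, p / 2, 1 - p / 2)
}
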