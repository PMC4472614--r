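log_stage <- function(verbose, ...) {
  if (verbose) message("[stromanet] ", ...)
}

write_result_tables <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    obj <- bundle[[nm]]
    if (is.data.frame(obj)) {
      utils::write.table(obj, file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (inherits(obj, "gene_set")) {
      write_gmt(obj, file.path(out_dir, paste0(nm, ".gmt")))
    }
  }
  invisible(out_dir)
}

#' Confrontation analysis end to end
#'
#' The self-controlled contrast: absent-gene filter, paired pre/post
#' differential expression across all lines, top-N DEG list, internal
#' connectivity of the list, network enrichment against a functional gene
#' set collection, and -- when a TF-target map is supplied -- single-gene TF
#' enrichment plus correlation-based validation of the TF-DEG pairs.
#'
#' @param study An [expression_study] with paired pre/post samples.
#' @param network A [gene_network] (the global functional-coupling network).
#' @param fgs_list List of [gene_set] objects (the FGS collection).
#' @param tf_map Optional [tf_target_map].
#' @param top_n Size of the DEG list used as AGS (default 300).
#' @param min_links,nea_fdr Significance rule of the batch NEA (defaults 5
#'   links, FDR 0.1).
#' @param tf_fdr,tf_min_links Significance rule for TFs (defaults 0.01, 3).
#' @param corr_fdr FDR for the TF-target correlation validation.
#' @param n_null_draws Random-pair draws for the correlation baseline.
#' @param mean_threshold,var_threshold Absent-gene filter thresholds.
#' @param seed Integer seed (used by the correlation baseline).
#' @param out_dir Optional directory: result tables are written as TSV/GMT.
#' @param verbose Log stage-by-stage counts to stderr.
#' @return List with elements `n_genes_kept`, `removed_genes`, `de`, `ags`,
#'   `internal`, `nea`, and (with a TF map) `tf_nea`, `tf_excess`.
#' @export
run_confrontation <- function(study, network, fgs_list, tf_map = NULL,
                              top_n = 300L, min_links = 5L, nea_fdr = 0.1,
                              tf_fdr = 0.01, tf_min_links = 3L,
                              corr_fdr = 0.05, n_null_draws = 200L,
                              mean_threshold = 4, var_threshold = 0.1,
                              seed = 1L, out_dir = NULL, verbose = TRUE) {
  if (inherits(fgs_list, "gene_set")) fgs_list <- list(fgs_list)
  if (length(fgs_list) == 0L) stop("run_confrontation: empty FGS collection")
  flt <- filter_absent(study, mean_threshold, var_threshold)
  log_stage(verbose, "filter_absent: removed ", length(flt$removed),
            " genes, kept ", nrow(flt$study$matrix))
  de <- differential_expression(flt$study, contrast = "condition",
                                paired = TRUE)
  log_stage(verbose, "differential_expression: ", sum(de$q < 0.05),
            " genes at q < 0.05")
  ags <- top_degs(de, top_n, id = paste0("confrontation_top", top_n))
  internal <- internal_connectivity(network, ags)
  log_stage(verbose, "internal_connectivity: z = ",
            sprintf("%.2f", internal$z), ", p = ",
            sprintf("%.3g", internal$p))
  nea <- nea_batch(network, ags, fgs_list, min_links = min_links,
                   fdr_threshold = nea_fdr)
  log_stage(verbose, "nea_batch: ", sum(nea$significant), " of ", nrow(nea),
            " FGS significant")
  bundle <- list(n_genes_kept = nrow(flt$study$matrix),
                 removed_genes = flt$removed, de = de, ags = ags,
                 internal = internal, nea = nea)
  if (!is.null(tf_map)) {
    bundle$tf_nea <- tf_enrichment(tf_map, ags, fdr_threshold = tf_fdr,
                                   min_links = tf_min_links)
    log_stage(verbose, "tf_enrichment: ", sum(bundle$tf_nea$significant),
              " TF(s) significant")
    bundle$tf_excess <- correlated_pair_excess(flt$study, tf_map,
                                               corr_fdr = corr_fdr,
                                               n_null_draws = n_null_draws,
                                               seed = seed)
    log_stage(verbose, "correlated_pair_excess: fold ",
              sprintf("%.2f", bundle$tf_excess$fold_excess))
  }
  if (!is.null(out_dir)) write_result_tables(bundle, out_dir)
  bundle
}

fold_change_degs <- function(study, pair, when, n, id) {
  s <- study$samples
  col_of <- function(line) {
    i <- which(s$line_id == line & s$condition == when)
    if (length(i) != 1L) stop("fold_change_degs: no unique '", when,
                              "' sample for line '", line, "'")
    i
  }
  d <- abs(study$matrix[, col_of(pair[1])] - study$matrix[, col_of(pair[2])])
  gene_set(id, names(sort(d, decreasing = TRUE))[seq_len(n)])
}

#' Inhibitory-capacity analysis end to end
#'
#' The between-line contrast at a chosen condition: absent-gene filter,
#' independent (Welch) differential expression of high- vs low-inhibitory
#' lines, top-N DEG list, internal connectivity and network enrichment
#' against the FGS collection. Optionally, per-pair DEG lists (top-N genes
#' by absolute fold change between two named lines, e.g. an in vitro pair
#' and an ex vivo pair) are scored separately and the Spearman correlation
#' of their pathway z-score vectors is reported -- the congruence check
#' between model systems.
#'
#' @inheritParams run_confrontation
#' @param condition Condition at which lines are compared (`"pre"` or
#'   `"post"`).
#' @param pairs Optional list of two length-2 character vectors of line ids
#'   (each `c(low, high)` or any two lines to contrast by fold change).
#' @return List with `n_genes_kept`, `de`, `ags`, `internal`, `nea`, and,
#'   when `pairs` is given, `pair_ags` (list of gene sets), `pair_nea`
#'   (list of `nea_result`), `pathway_score_correlation` (one-row data
#'   frame).
#' @export
run_inhibition <- function(study, network, fgs_list,
                           condition = c("pre", "post"), top_n = 300L,
                           min_links = 5L, nea_fdr = 0.1, pairs = NULL,
                           mean_threshold = 4, var_threshold = 0.1,
                           out_dir = NULL, verbose = TRUE) {
  condition <- match.arg(condition)
  if (inherits(fgs_list, "gene_set")) fgs_list <- list(fgs_list)
  if (length(fgs_list) == 0L) stop("run_inhibition: empty FGS collection")
  flt <- filter_absent(study, mean_threshold, var_threshold)
  sub <- subset_samples(flt$study, flt$study$samples$condition == condition)
  n_high <- sum(sub$samples$inhibition == "high")
  n_low <- sum(sub$samples$inhibition == "low")
  if (n_high != n_low || n_high < 2L) {
    stop("run_inhibition: unbalanced inhibition class annotation (",
         n_high, " high vs ", n_low, " low)")
  }
  log_stage(verbose, "inhibition contrast at '", condition, "': ",
            n_high, " high vs ", n_low, " low lines, ",
            nrow(sub$matrix), " genes")
  de <- differential_expression(sub, contrast = "inhibition", paired = FALSE)
  ags <- top_degs(de, top_n, id = paste0("inhibition_", condition,
                                         "_top", top_n))
  internal <- internal_connectivity(network, ags)
  nea <- nea_batch(network, ags, fgs_list, min_links = min_links,
                   fdr_threshold = nea_fdr)
  log_stage(verbose, "nea_batch: ", sum(nea$significant), " of ", nrow(nea),
            " FGS significant")
  bundle <- list(n_genes_kept = nrow(flt$study$matrix), de = de, ags = ags,
                 internal = internal, nea = nea)
  if (!is.null(pairs)) {
    stopifnot(length(pairs) == 2L)
    bundle$pair_ags <- lapply(seq_along(pairs), function(i) {
      fold_change_degs(flt$study, pairs[[i]], condition, top_n,
                       id = paste0("pair_", paste(pairs[[i]], collapse = "_vs_")))
    })
    bundle$pair_nea <- lapply(bundle$pair_ags, function(a) {
      nea_batch(network, a, fgs_list, min_links = min_links,
                fdr_threshold = nea_fdr)
    })
    z1 <- bundle$pair_nea[[1]]$z
    z2 <- bundle$pair_nea[[2]]$z
    ct <- suppressWarnings(stats::cor.test(z1, z2, method = "spearman"))
    bundle$pathway_score_correlation <- data.frame(
      pair_a = bundle$pair_ags[[1]]$id, pair_b = bundle$pair_ags[[2]]$id,
      method = "spearman", r = unname(ct$estimate), p = ct$p.value,
      stringsAsFactors = FALSE)
    log_stage(verbose, "pathway-score correlation: r = ",
              sprintf("%.3f", ct$estimate))
  }
  if (!is.null(out_dir)) write_result_tables(bundle, out_dir)
  bundle
}
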