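#!/usr/bin/env Rscript
# Confrontation contrast: which genes respond when fibroblasts meet cancer
# cells, and which pathways / transcription factors organize that response.
# Reads the simulated inputs of 01_simulate_study.R from their text files,
# exactly as a real study would be read.

suppressMessages(library(stromanet))

inp <- "results/synthetic"
stopifnot(file.exists(file.path(inp, "expression.tsv")))

study <- load_expression(file.path(inp, "expression.tsv"),
                         file.path(inp, "samples.tsv"))
network <- load_network(file.path(inp, "network.tsv"))
fgs <- load_gene_sets(file.path(inp, "pathways.gmt"))
tf_map <- load_tf_map(file.path(inp, "tf_map.tsv"))
truth <- load_gene_sets(file.path(inp, "truth.gmt"))

b <- run_confrontation(study, network, fgs, tf_map = tf_map,
                       top_n = 300, seed = 2,
                       out_dir = "results/confrontation")

recall <- mean(truth$TRUTH_CONFRONTATION$members %in% b$ags$members)
sig <- b$nea[b$nea$significant & b$nea$z > 0, ]
cat("\n--- Confrontation analysis ---\n")
cat(sprintf("Genes kept after absent filter: %d (removed %d)\n",
            b$n_genes_kept, length(b$removed_genes)))
cat(sprintf("DEGs at q < 0.05: %d; top-300 recall of planted DEGs: %.2f\n",
            sum(b$de$q < 0.05), recall))
cat(sprintf("Internal connectivity of the DEG list: z = %.2f (p = %.3g)\n",
            b$internal$z, b$internal$p))
cat(sprintf("Pathways enriched (FDR < 0.1, >= 5 links): %s\n",
            paste(sig$fgs_id, collapse = ", ")))
cat(sprintf("TFs called (FDR < 0.01, >= 3 links): %d\n",
            sum(b$tf_nea$significant)))
cat(sprintf("TF-target correlated-pair excess: %.1f-fold (%d of %d pairs)\n",
            b$tf_excess$fold_excess, b$tf_excess$n_correlated,
            b$tf_excess$n_pairs_tested))
cat("Tables written under results/confrontation\n")
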