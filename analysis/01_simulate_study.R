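#!/usr/bin/env Rscript
# Generates the synthetic confrontation study that the downstream analysis
# scripts consume, and writes every input in the same text formats a real
# study would arrive in: expression matrix + sample sheet (TSV), global
# network (edge-list TSV), functional gene sets (GMT), TF-target map (TSV),
# survival cohorts (per-cohort expression + survival TSV).

suppressMessages(library(stromanet))

seed <- 1L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Simulating the paired 8-line confrontation study (6000 genes) ...")
fs <- suppressWarnings(synth_full_study(synth_spec(n_genes = 6000, seed = seed)))

message("Planting TF-target correlations on top of the study ...")
tt <- synth_tf_targets(fs$study, n_tfs = 50, targets_per_tf = 12,
                       correlated_fraction = 0.10, seed = seed + 10)
study <- tt$study

# one TF that specifically targets confrontation DEGs, so the single-gene
# enrichment mode has a planted positive
set.seed(seed + 11)
deg_tf <- setdiff(rownames(study$matrix),
                  c(tt$tf_map$tf, tt$tf_map$target, fs$truth$absent))[1]
tf_map <- tf_target_map(c(tt$tf_map$tf, rep(deg_tf, 12)),
                        c(tt$tf_map$target,
                          sample(fs$truth$confrontation, 12)))

write.table(data.frame(gene = rownames(study$matrix), study$matrix,
                       check.names = FALSE),
            file.path(out, "expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$samples, file.path(out, "samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_network(fs$network, file.path(out, "network.tsv"))
write_gmt(fs$fgs, file.path(out, "pathways.gmt"))
write.table(tf_map, file.path(out, "tf_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

# ground truth, for the evaluation steps of the later scripts
write_gmt(list(gene_set("TRUTH_CONFRONTATION", fs$truth$confrontation),
               gene_set("TRUTH_INHIBITION", fs$truth$inhibition),
               gene_set("TRUTH_ABSENT", fs$truth$absent)),
          file.path(out, "truth.gmt"))
writeLines(tt$tf_map$target[tt$truth], file.path(out, "truth_tf_targets.txt"))

message("Simulating 6 survival cohorts (1000 genes x 120 patients) ...")
sv <- synth_survival(n_cohorts = 6, n_patients = 120, n_genes = 1000,
                     n_prognostic = 150, hazard_ratio = 2,
                     censor_rate = 0.3, seed = seed + 20)
surv_dir <- file.path(out, "survival")
dir.create(surv_dir, showWarnings = FALSE)
for (co in sv$cohorts) {
  write.table(data.frame(patient_id = colnames(co$expression),
                         time = co$time, event = co$event),
              file.path(surv_dir, paste0(co$cohort_id, "_survival.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = rownames(co$expression), co$expression,
                         check.names = FALSE),
              file.path(surv_dir, paste0(co$cohort_id, "_expression.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
writeLines(sv$prognostic, file.path(surv_dir, "truth_prognostic.txt"))

message("Inputs written under ", out)
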