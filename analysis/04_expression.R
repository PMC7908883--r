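#!/usr/bin/env Rscript
# Expression profiling: expressed-gene calls (TPM > 0.5), k-means clustering
# on log2 per-tissue means with tissue-preference labels, and stress
# log-ratios with induction flags checked against the planted truth.

suppressMessages({library(polyfam); library(data.table)})

family <- fread("data/study/family.tsv")
em <- read_tpm_matrix("data/study/tpm.tsv", "data/study/samples.tsv")
fam_em <- expression_matrix(
  em$values[intersect(rownames(em$values), family$gene_id), , drop = FALSE],
  em$meta)

calls <- call_expressed(fam_em, threshold = 0.5)
cat(sprintf("expressed: %d/%d family genes (TPM > 0.5 in >= 1 sample)\n",
            sum(calls$expressed), nrow(calls)))

clus <- cluster_expression(fam_em, k = 10, seed = 1)
pref <- table(clus$cluster_preference$preference)
cat("cluster preferences:", paste(names(pref), pref, sep = "=", collapse = ", "), "\n")

stress <- fread("data/study/stress.tsv")
stress[, lfc := stress_log_ratio(stress_tpm, control_tpm)]
fl <- flag_induced(stress[, .(gene_id, condition, lfc)], lfc_min = 1)
truth <- fread("data/study/truth_stress.tsv")
m <- merge(fl$calls, truth, by = c("gene_id", "condition"))
cat(sprintf("induced calls: %d (planted %d; exact agreement: %s)\n",
            sum(fl$calls$induced), sum(truth$induced),
            all(m$induced.x == m$induced.y)))

dir.create("results", showWarnings = FALSE)
write_tsv(calls, "results/expressed_calls.tsv")
write_tsv(clus$assignments, "results/clusters.tsv")
write_tsv(fl$calls, "results/stress_lfc.tsv")
write_tsv(fl$summary, "results/stress_induced.tsv")
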