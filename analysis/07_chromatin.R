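#!/usr/bin/env Rscript
# Chromatin marks: credible peaks from replicate overlap (>= 1 bp), gene-body
# mark assignment, and the mark x expression cross-tabulation.

suppressMessages({library(polyfam); library(data.table)})

genes <- read_gff3("data/study/genome.gff3")
family <- fread("data/study/family.tsv")
fam_genes <- genes[gene_id %in% family$gene_id]

r1 <- read_bed("data/study/peaks_rep1.bed")[, mark := name]
r2 <- read_bed("data/study/peaks_rep2.bed")[, mark := name]
cred <- credible_peaks(r1, r2)
truth <- fread("data/study/truth_peaks.tsv")
cat(sprintf("credible peaks: %d (planted shared: %d; exact match: %s)\n",
            nrow(cred), nrow(truth),
            isTRUE(all.equal(setorder(cred[, .(chrom, start, end)], chrom, start),
                             setorder(truth, chrom, start)))))

em <- read_tpm_matrix("data/study/tpm.tsv", "data/study/samples.tsv")
fam_em <- expression_matrix(
  em$values[intersect(rownames(em$values), family$gene_id), , drop = FALSE],
  em$meta)
calls <- call_expressed(fam_em, threshold = 0.5)

asg <- assign_marks(cred, fam_genes)
tab <- mark_expression_table(asg, calls)
print(tab)
marked_truth <- readLines("data/study/truth_marked_genes.txt")
cat(sprintf("marked genes: %d found, %d planted; identical: %s\n",
            sum(asg$has_mark), length(marked_truth),
            setequal(asg[has_mark == TRUE, gene_id], marked_truth)))

dir.create("results", showWarnings = FALSE)
write_bed(cred[, .(chrom, start, end, name = mark, strand = ".")],
          "results/credible_peaks.bed")
write_tsv(asg, "results/mark_assignments.tsv")
write_tsv(tab, "results/mark_expression_table.tsv")
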