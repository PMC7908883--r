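#!/usr/bin/env Rscript
# Duplication and selection: tandem clusters by intervening-gene count
# (<= 3), chromosomal-segment enrichment chi-square, and NG86 Ka/Ks over the
# planted substitution classes. Also recomputes the wheat-scale centromeric
# depletion test from the published family counts (188 genes, 3 in segment
# C, genome share 10.67%).

suppressMessages({library(polyfam); library(data.table)})

genes <- read_gff3("data/study/genome.gff3")
family <- fread("data/study/family.tsv")
fam_genes <- genes[gene_id %in% family$gene_id]

cl <- find_tandem_clusters(fam_genes, max_gap = 3)
truth_t <- fread("data/study/truth_tandem.tsv")
cat(sprintf("tandem clusters: %d found, %d planted\n",
            length(unique(cl$cluster_id)), nrow(truth_t)))

segs <- read_bed("data/study/segments.bed")
fam_seg <- segment_assign(fam_genes, segs)
all_seg <- segment_assign(genes, segs)
lv <- unique(segs$name)
enr <- segment_enrichment(
  setNames(as.integer(table(factor(fam_seg$segment, lv))), lv),
  n = nrow(fam_seg),
  genome_props = setNames(as.numeric(prop.table(table(factor(all_seg$segment, lv)))), lv))
print(enr)

wheat <- segment_enrichment(c(C = 3L), n = 188, genome_props = c(C = 0.1067))
cat(sprintf("wheat-scale segment C: %.2f%% vs %.2f%%, chi2=%.2f, p=%.2g (%s)\n",
            100 * wheat$prop_family, 100 * wheat$prop_genome,
            wheat$chi2, wheat$p, wheat$direction))

pairs <- fread("data/study/cds_pairs.tsv")
kk <- kaks_table(pairs)
kk[, class := pairs$class[match(pair_id, pairs$pair_id)]]
cat("Ka/Ks by planted class:\n")
print(kk[, .(mean_ka = mean(ka), mean_ks = mean(ks),
             mean_ratio = mean(ratio, na.rm = TRUE)), by = class])

dir.create("results", showWarnings = FALSE)
write_tsv(cl, "results/tandem_clusters.tsv")
write_tsv(enr, "results/segment_enrichment.tsv")
write_tsv(kk, "results/kaks.tsv")
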