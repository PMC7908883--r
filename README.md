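# polyfam

Genome-wide characterization of a gene family in an allohexaploid genome
(bread wheat, subgenomes A/B/D), packaged as a tested analysis pipeline.
It covers the full arc of a family study:

* **membership** — homology-hit filtering (E ≤ 1e-5, identity ≥ 60,
  query coverage ≥ 50%), conserved-domain confirmation, naming by
  chromosomal order, molecular weight and isoelectric point;
* **homoeolog triads** — 1:1:1 detection, retention rate, and per-tissue
  expression-bias classification by shortest Euclidean distance of the
  within-triad relative abundances (rA, rB, rD) to seven archetypes
  (balanced, A/B/D-dominant, A/B/D-suppressed), with ternary-plot
  coordinates;
* **expression** — expressed calls (TPM > 0.5), reproducible k-means
  tissue-preference clustering, stress log2((stress+0.5)/(control+0.5))
  ratios and induction flags;
* **duplication & selection** — tandem clusters (≤ 3 intervening genes),
  chromosomal-segment χ² enrichment, Nei–Gojobori (1986) Ka/Ks with
  Jukes–Cantor correction;
* **miRNA & degradome** — position-weighted duplex scoring (mismatch 1,
  G:U 0.5, gap 1, doubled at miRNA positions 2–13; retain score ≤ 4.5),
  cleavage site opposite miRNA position 10, T-plot categories 0–4;
* **chromatin** — credible peaks (≥ 1 bp replicate overlap), gene-body
  mark assignment, mark × expression tables;
* **synthetic data** — a generator for every input with planted ground
  truth, so the whole pipeline is testable offline.

The methods vignette (`vignettes/methods.Rmd`) documents every model,
threshold and design choice in detail.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R`, then `02`…`07`). The core of the
triad analysis, in a few lines:

```r
library(polyfam)
library(data.table)

sim_config(seed = 1) |> simulate_study("data/study")

genes  <- read_gff3("data/study/genome.gff3")
family <- fread("data/study/family.tsv")
groups <- fread("data/study/homoeolog_groups.tsv")
em     <- read_tpm_matrix("data/study/tpm.tsv", "data/study/samples.tsv")

tri <- detect_triads(genes[gene_id %in% family$gene_id], groups)
triad_retention_rate(nrow(family), nrow(tri$triads))$fraction
#> [1] 0.8

calls <- classify_triads(tri$triads, em, min_total = 0.5)
bias_summary(calls)[tissue == "root"]
```

which prints (seed 1):

```
triads: 44 of 61 groups (retention 132/165 = 80.0%)
root      balanced 58.5%, D-suppressed 22.0% (n=41)
planted-category recovery: 1.000 (filter agreement: TRUE)
```

Read: 132 of the 165 family genes sit in 1:1:1 triads (80%, the planted
retention); in roots, 58.5% of the 41 classifiable triads are balanced
across the three subgenomes; every planted bias category and every triad
planted below the 0.5 summed-TPM filter is recovered exactly. A single
classification is just as direct:

```r
classify_bias(18, 1, 1)$category
#> [1] "A-dominant"
```

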