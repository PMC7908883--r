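#!/usr/bin/env Rscript
# Generate the synthetic study: a 21-chromosome allohexaploid genome with a
# gene family planted as triads/dyads/singletons plus tandem clusters, TPM
# matrices with planted homoeolog-bias categories, stress pairs, aligned CDS
# pairs, a miRNA with planted target sites and degradome spikes, and
# replicate ChIP peak sets. All downstream scripts read data/study/.

suppressMessages(library(polyfam))

seed <- 1
cfg <- sim_config(seed = seed)
dir.create("results", showWarnings = FALSE)
sim <- simulate_study(cfg, "data/study")

cat(sprintf("seed %d: wrote data/study with %d genes (%d family members)\n",
            seed, nrow(sim$genome$genes), nrow(sim$genome$family)))
cat(sprintf("planted: %d triads, %d tandem extras, %d transcripts (%d with miRNA sites), %d/%d shared peaks\n",
            nrow(sim$genome$truth$triads),
            nrow(sim$genome$truth$tandem_clusters),
            length(sim$degradome$transcripts),
            sum(sim$degradome$truth$has_site),
            nrow(sim$peaks$truth), nrow(sim$peaks$rep1)))
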