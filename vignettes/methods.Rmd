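---
title: "Methods: gene-family characterization in an allohexaploid genome"
author: "polyfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization in an allohexaploid genome}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polyfam re-implements, as a tested pipeline, the sequence of analyses used
to characterize a transcription-factor gene family genome-wide in bread
wheat: membership filtering, homoeolog-triad expression bias, tissue and
stress expression profiling, duplication and selection statistics, miRNA
target prediction with degradome evidence, and histone-mark assignment.
This vignette is the package's own account of each method, its
assumptions, and the choices made where the design was genuinely open.

## Coordinate conventions

Every interval inside the package is 0-based half-open. GFF3 (1-based
closed) is converted once at the boundary by `read_gff3()`; BED input is
already in the internal convention and is taken verbatim. One internal
convention eliminates a whole class of off-by-one errors at module
boundaries. Strand is carried but ignored by all overlap logic: gene-body
/ peak overlap is strand-agnostic, matching how histone-mark targets are
defined. Chromosome names of the form `4A` are parsed into a homoeologous
group number (4) and a subgenome letter (A); the pattern is configurable
for other nomenclatures.

## Family membership

A query protein becomes a candidate when **one single homology hit**
simultaneously satisfies E-value <= 1e-5, percent identity >= 60 and query
coverage >= 50%. All three boundaries are inclusive; coverage is the
aligned query span over the query length (the query sequences are the
known family proteins, so the query is the natural denominator).
Candidates are confirmed when every required evidence source (by default
only the HMM profile search; SMART/PFAM/CDD evidence can be added to the
requirement) reports a *complete* domain at E <= 1e-5. Truncated or absent
domains eliminate a candidate, and candidates without evidence rows are
reported in a rejection log rather than silently dropped. Whether the
original membership filters were applied per hit or per best hit is not
derivable from the description we work from; the per-hit reading is used
and flagged in the output.

Confirmed genes are named `<prefix>1..n` by chromosomal order, sorting on
(group number, subgenome letter, start position) with ties broken by gene
id so that naming is a deterministic bijection invariant under input
order. Molecular weight uses average residue masses plus one water;
isoelectric point is the pH at which the Henderson–Hasselbalch net charge
crosses zero, found by bisection on [0, 14] to |charge| < 1e-4. The pKa
table (N-term 8.0, C-term 3.1, Cys 8.3, Asp 3.65, Glu 4.25, His 6.0, Lys
10.53, Arg 12.48, Tyr 10.07) is configuration, not hard-coded: the
upstream tool is named in the source work but its constants are not, so a
single documented table ships as the default and the test suite checks the
bisection against a 1e-3-step grid-search oracle rather than against any
particular constant set.

## Homoeolog triads and expression bias

A homoeologous group with exactly one member on each of the A, B and D
subgenomes is a 1:1:1 triad; all other cardinalities are reported as
non-triads. Retention is 3 x triads / family size.

For each triad and tissue the three homoeolog TPMs (averaged over that
tissue's samples first; a per-sample-then-majority alternative exists) are
normalized to relative abundances (rA, rB, rD) summing to 1, and the triad
is assigned the nearest of seven archetypes by plain Euclidean distance in
3-space:

* balanced (1/3, 1/3, 1/3);
* A/B/D-dominant: all expression from one subgenome, e.g. (1, 0, 0);
* A/B/D-suppressed: one subgenome silent, the other two equal, e.g.
  (0, 1/2, 1/2).

The archetype vectors follow the convention of the homoeolog-bias
framework this analysis descends from (dominant = single-copy expression,
suppressed = equal sharing by the other two); they are exposed by
`bias_archetypes()` so alternates can be tested. "Normalized expression"
is read as within-triad relative abundance per sample — the only reading
under which ternary plots of triads are well-defined — not z-scoring
across samples. Triads with summed TPM below 0.5 are excluded before
classification. Ties in the distance argmin occur only on measure-zero
inputs but are made deterministic: balanced first, then dominants A, B, D,
then suppressed A, B, D. Ternary plot coordinates use the standard simplex
map x = rB + rD/2, y = (sqrt(3)/2) rD, which is invertible on the simplex.

Because a suppression share can be quoted per triad x tissue call or per
triad aggregated, `bias_summary()` reports per-tissue tables **and** an
explicit `tissue = "all"` aggregate over calls, so both units are
available and labelled.

## Expression, clustering, stress

A gene is *expressed* when its maximum TPM over the considered samples is
strictly greater than 0.5. Clustering uses per-tissue mean TPM,
log2(x+1)-transformed (the source heatmaps were drawn unscaled, so no
z-scoring), k-means with k = 10 by default. Base R's `kmeans()` supplies
the optimizer; seeding is k-means++ with at least 10 restarts under a
fixed seed, keeping the best within-cluster sum of squares, so runs are
bit-reproducible. Each cluster's preference label comes from its centroid
back on the TPM scale: `not_expressed` when every tissue-class mean is at
or below 0.5; a class label when the top class mean is at least twice
every other; otherwise `ubiquitous`. Root tissue counts as vegetative for
this call (roots are vegetative tissue) so the label set stays
{reproductive, vegetative, ubiquitous, not_expressed}; both the dominance
ratio and the transform are configurable because the original cluster-to-
preference rule is not specified anywhere we can consult.

Stress response is the log2 ratio of (stress + 0.5) over (control + 0.5);
the 0.5 pseudo-TPM keeps zeros finite and makes the statistic
antisymmetric under swapping the two conditions. Induction is called at
log2 fold change >= 1 by default — the source reports induction only
qualitatively, so the threshold is the package's own documented default.

## Duplication and selection

Tandem clusters chain family genes on the same chromosome whose
genome-order ranks (ranks among **all** annotated genes, not just family
members) differ by at most `max_gap + 1`, i.e. at most 3 intervening
genes; connected components of size >= 2 are reported. Whether the
intervening-gene count in the original rule includes family genes is
undefined there; intervening *annotated* genes is used and flagged.

Segment enrichment per chromosomal segment class (R1/R2a/C/R2b/R3, an
input BED partition) is a one-degree-of-freedom Pearson goodness-of-fit
test of the family's in/out split against the genome-wide proportion,
without continuity correction; when an expected count drops below 1 an
exact binomial test is substituted with a warning. A goodness-of-fit
rather than 2x2 contingency reading was chosen; the binomial oracle in the
tests confirms direction and significance agree at alpha = 0.001 at the
family sizes involved.

Ka/Ks is Nei–Gojobori (1986) with Jukes–Cantor correction: per-codon
synonymous site fractions averaged over both sequences; pathway-averaged
difference counts for codons differing at more than one position (pathways
through stop codons are discarded when any stop-free pathway exists);
d = -3/4 ln(1 - 4p/3), with an explicit error when p >= 3/4. Mutations
*to* stop codons count as nonsynonymous in site counting. The original
analysis used a model-averaged estimator behind an alignment pipeline;
NG86 + JC is this package's deterministic, oracle-verifiable method, so
per-subfamily Ka/Ks distributions are reproduced qualitatively (purifying
selection; no pair above 1), not numerically. Alignments are inputs:
codon-alignment construction and synteny inference are out of scope, and
segmental duplicate pairs are declared from the input homoeolog/paralog
table.

## miRNA targets and degradome evidence

Duplexes are scored by antiparallel complementarity from the miRNA 5'
end: mismatch 1.0, G:U wobble 0.5, gap 1.0, with every penalty doubled at
miRNA positions 2–13, and more than one consecutive gap forbidden. Only
the 4.5 retention cutoff is printed in the work this descends from; the
penalty scheme is the Allen-style convention its named tool popularized,
adopted as the documented, fully configurable default. The cutoff is
inclusive: a score of exactly 4.5 is retained, since only scores *above*
4.5 are removed. The transcript scan is an exhaustive ungapped window scan
(desk-scale transcripts make this affordable and oracle-exact);
single-gap duplexes are supported by `score_duplex()` for windows one base
shorter or longer than the miRNA. The predicted cleavage site is the
transcript position paired with miRNA position 10 (cut between 10
and 11).

Degradome support is graded with c = the 5'-end count at the cleavage
site, M = the transcript-wide maximum and med = the median over occupied
positions (positions with >= 1 read — the occupied-only median is this
package's recorded choice): `none` if c = 0; 4 if c = 1; 0 if c > 1 and c
is the unique maximum; 1 if c equals a shared maximum; 2 if
1 < c < M and c > med; 3 if 1 < c <= med.

## Chromatin marks

A peak is *credible* when it overlaps a peak from the other biological
replicate by at least 1 bp (half-open arithmetic, so touching intervals do
not overlap). The emitted interval is the union of the connected
overlapping replicate peaks — union rather than intersection so gene-body
overlap is never under-called; intersection is available. A gene is a
target of a mark when any credible peak overlaps its full genomic span
("gene body"; no promoter window is modelled, and any-overlap rather than
summit-containment is used). Marks are presence/absence only; peak height
is not modelled. The mark x expression cross-tab stratifies marked
fractions by the expressed call at TPM > 0.5. Upstream read processing
and peak calling are out of scope; peaks are BED inputs.

## The synthetic study

`sim_config()` defines the generator defaults, which are the package's
study conditions and are not tuned per run:

* genome: 21 chromosomes (7 groups x A/B/D), 400 genes per chromosome at
  regular 5 kb spacing; 44 triad groups, 8 dyads, 9 singletons and 8
  tandem extras planted 2 ranks after an anchor — 132 of 165 family genes
  in triads, retention 0.800, mirroring the ~79.8% retention of the study
  family; family slots are kept >= 6 ranks apart so no accidental tandem
  chains arise.
* bias mixture: balanced 0.62, D-suppressed 0.16, A/B-suppressed
  0.08/0.07, dominants 0.025/0.025/0.02 — the balanced share (~62%) and
  elevated D-suppression (~16%) reported for the family.
* simplex noise is a Dirichlet draw centred on the planted archetype,
  alpha = concentration x archetype + 0.02 (the 0.02 floor keeps zero
  components proper); concentration 200 by default, infinite concentration
  reproduces the archetype exactly. Totals are log-normal (heavy-tailed
  like real TPM). Replicates share each triad's relative abundances and
  differ only by a common magnitude factor: the noise model deliberately
  separates the simplex signal (Dirichlet) from magnitude noise
  (log-normal), which makes zero-concentration recovery provably exact.
  Real data also carry per-homoeolog measurement noise across replicates;
  passing recovery tests therefore demonstrates correctness of the
  classifier, not robustness to every noise source in real RNA-seq.
* a 5% share of triad x tissue cells is planted below the 0.5 summed-TPM
  filter (with exact totals, so the filter must recover them verbatim),
  and 35% of non-triad family genes are silent everywhere, giving both
  expression strata.
* CDS pairs: 300 codons, 90 planted substitutions (~10% divergence — a
  typical CDS length with enough synonymous events for a stable
  Jukes–Cantor estimate; at much smaller counts the Ka/Ks ratio estimator
  is heavy-tailed). Synonymous-only and nonsynonymous-only classes touch
  each codon at most once so the planted class stays pure under pathway
  counting; the equal-rate class is an unconstrained uniform substitution
  process (stop-creating draws redrawn), under which NG86 should average
  ~1.
* degradome: 21-nt miRNA, 500-nt transcripts, 30% with a perfect
  reverse-complement site and a dominant unique 5'-end spike (count 30)
  exactly opposite miRNA position 10 over sparse background counts 1–3.
* peaks: 40 per mark, 60% shared with sub-width jitter (guaranteeing
  >= 1 bp overlap), privates on disjoint slots; when gene targeting is
  requested, 30% of family genes carry a shared peak in the gene body.

Every generator is deterministic given the seed, restores the caller's
RNG state, and emits its ground truth alongside the data.

## Problem sizes and numerical choices

The default study (8 400 genes, 44 triads x 4 tissues x 2 replicates, 15
CDS pairs, 20 transcripts, 80 peaks) runs the full pipeline in under a
minute; the oracle checks use 10 000 simplex points, exhaustive 8-nt
duplex enumeration (65 536 windows), all count profiles of length <= 6
over counts 0–3, and 200 equal-rate CDS replicates. Degenerate inputs are
errors, not silent results: negative TPM, invalid intervals, genes outside
the segment partition, Jukes–Cantor proportions >= 3/4, cleavage sites
outside a profile. The distance argmin tie-break, the naming tie-break and
the k-means seeding are all fixed so that identical inputs give
byte-identical outputs.

## Known limitations

* NG86 + JC stands in for model-averaged Ka/Ks; absolute values are not
  comparable to codon-model estimators at high divergence.
* The duplex scan is ungapped at the scan level; gapped sites are only
  scored when a candidate window is supplied explicitly.
* The synthetic genome has uniform gene spacing and equal chromosome
  sizes; positional statistics on it exercise correctness, not realistic
  wheat karyotype structure.
* Subfamily assignment, phylogenetics, localization prediction and all
  read-level processing are out of scope; their outputs are inputs here.
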