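#' Tandem duplication, segment enrichment, Ka/Ks
#'
#' @name duplication_evolution
NULL

#' Find tandem-duplication clusters by intervening-gene count
#'
#' Two family genes on the same chromosome are linked when separated by at
#' most `max_gap` intervening annotated genes, i.e. when their genome-order
#' ranks differ by at most `max_gap + 1`. Connected components
#' (single-linkage chains) of size >= 2 are clusters.
#'
#' @param family_genes data.table with `gene_id`, `chrom`, `rank` (rank among
#'   ALL annotated genes on the chromosome, from [read_gff3()] of the full
#'   annotation).
#' @param max_gap maximum intervening genes (default 3).
#' @return data.table: `cluster_id`, `chrom`, `gene_id`, `rank`, ordered by
#'   rank within cluster; zero rows when no cluster.
#' @export
find_tandem_clusters <- function(family_genes, max_gap = 3) {
  g <- as.data.table(family_genes)
  if (anyNA(g$rank)) stop("family gene without genome-order rank: ",
                          g$gene_id[is.na(g$rank)][1])
  setorder(g, chrom, rank)
  out <- list()
  cid <- 0L
  for (ch in unique(g$chrom)) {
    rows <- g[chrom == ch]
    if (nrow(rows) < 2) next
    gap_break <- c(FALSE, diff(rows$rank) > max_gap + 1)
    comp <- cumsum(gap_break)
    for (cc in unique(comp)) {
      members <- rows[comp == cc]
      if (nrow(members) >= 2) {
        cid <- cid + 1L
        out[[cid]] <- data.table(cluster_id = cid, chrom = ch,
                                 gene_id = members$gene_id, rank = members$rank)
      }
    }
  }
  if (!length(out)) {
    return(data.table(cluster_id = integer(), chrom = character(),
                      gene_id = character(), rank = integer()))
  }
  rbindlist(out)
}

#' Assign genes to chromosomal segments
#'
#' Segments (e.g. R1/R2a/C/R2b/R3) must partition each chromosome
#' contiguously; a gene belongs to the segment containing its start
#' coordinate (half-open intervals, so a gene starting exactly at a boundary
#' belongs to the segment beginning there).
#'
#' @param genes data.table with `gene_id`, `chrom`, `start`.
#' @param segments data.table with `chrom`, `start`, `end`, `name` (segment
#'   label), e.g. from [read_bed()].
#' @return data.table: `gene_id`, `chrom`, `start`, `segment`.
#' @export
segment_assign <- function(genes, segments) {
  genes <- as.data.table(genes)
  seg <- as.data.table(segments)
  setorder(seg, chrom, start)
  # partition check: contiguous, non-overlapping cover per chromosome
  seg[, {
    if (.N > 1 && any(start[-1] != end[-.N])) {
      stop("segments do not partition chromosome ", chrom[1],
           " (hole or overlap at ", start[-1][start[-1] != end[-.N]][1], ")")
    }
    NULL
  }, by = chrom]
  res <- lapply(seq_len(nrow(genes)), function(i) {
    s <- seg[chrom == genes$chrom[i] & start <= genes$start[i] & genes$start[i] < end]
    if (nrow(s) != 1) {
      stop("gene ", genes$gene_id[i], " at ", genes$chrom[i], ":", genes$start[i],
           " falls outside the segment partition")
    }
    s$name
  })
  data.table(gene_id = genes$gene_id, chrom = genes$chrom, start = genes$start,
             segment = unlist(res))
}

#' Segment enrichment / depletion chi-square tests
#'
#' For each segment class, a one-degree-of-freedom Pearson goodness-of-fit
#' test of the family's in/out-of-class split against the genome-wide
#' proportion, without continuity correction. When an expected count falls
#' below 1 an exact binomial test is substituted (with a warning).
#'
#' @param observed named integer vector: family gene count per segment class.
#' @param n family size (> 0).
#' @param genome_props named numeric vector: genome-wide gene proportion per
#'   class, same names as `observed`, each in (0, 1).
#' @return data.table: `segment`, `observed`, `expected`, `prop_family`,
#'   `prop_genome`, `chi2`, `p`, `direction` (enriched/depleted/none),
#'   `test` (chi2/binomial).
#' @export
segment_enrichment <- function(observed, n, genome_props) {
  stopifnot(n > 0, all(names(observed) %in% names(genome_props)))
  out <- lapply(names(observed), function(cl) {
    obs <- observed[[cl]]
    p <- genome_props[[cl]]
    stopifnot(obs >= 0, obs <= n, p > 0, p < 1)
    exp_in <- n * p
    direction <- if (obs > exp_in) "enriched" else if (obs < exp_in) "depleted" else "none"
    if (min(exp_in, n - exp_in) < 1) {
      warning("expected count < 1 for segment ", cl, "; exact binomial test substituted")
      bt <- binom.test(obs, n, p)
      data.table(segment = cl, observed = obs, expected = exp_in,
                 prop_family = obs / n, prop_genome = p,
                 chi2 = NA_real_, p = bt$p.value, direction = direction,
                 test = "binomial")
    } else {
      chi2 <- (obs - exp_in)^2 / exp_in + ((n - obs) - (n - exp_in))^2 / (n - exp_in)
      pv <- pchisq(chi2, df = 1, lower.tail = FALSE)
      data.table(segment = cl, observed = obs, expected = exp_in,
                 prop_family = obs / n, prop_genome = p,
                 chi2 = chi2, p = pv, direction = direction, test = "chi2")
    }
  })
  rbindlist(out)
}

# --- Nei-Gojobori (1986) Ka/Ks ---------------------------------------------

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.split_codons <- function(cds) {
  cds <- toupper(gsub("U", "T", cds))
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters (gap-free DNA required)")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# Synonymous site count of one codon: at each position, fraction of the three
# possible single-base changes that preserve the amino acid. Changes to stop
# codons count as nonsynonymous.
.syn_sites_codon <- function(codon, gc) {
  aa <- gc[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (gc[[mut]] == aa && gc[[mut]] != "*") s <- s + 1 / 3
    }
  }
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# codons. All orderings of the differing positions are enumerated; pathways
# passing through a stop codon are discarded unless every pathway does.
.codon_diffs <- function(c1, c2, gc) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    if (length(pos) == 2) list(pos, rev(pos)) else {
      p <- pos
      list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)], p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
    }
  }
  path_counts <- list()
  for (perm in perms) {
    cur <- c1; sd <- 0; nd <- 0; through_stop <- FALSE
    for (p in perm) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*" && nxt != c2) through_stop <- TRUE
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    path_counts[[length(path_counts) + 1]] <- list(sd = sd, nd = nd, stop = through_stop)
  }
  ok <- Filter(function(x) !x$stop, path_counts)
  if (!length(ok)) ok <- path_counts
  c(sd = mean(vapply(ok, `[[`, 0, "sd")), nd = mean(vapply(ok, `[[`, 0, "nd")))
}

#' Nei-Gojobori (1986) Ka/Ks for an aligned CDS pair
#'
#' Synonymous/nonsynonymous site fractions are computed per codon and
#' averaged over both sequences; differences for codons differing at more
#' than one position are averaged over mutational pathways (pathways through
#' stop codons discarded when avoidable); proportions are Jukes-Cantor
#' corrected, d = -3/4 ln(1 - 4p/3).
#'
#' @param cds_a,cds_b equal-length, gap-free, in-frame aligned CDS strings
#'   (DNA; no internal stop codons).
#' @return list: `ka`, `ks`, `ratio` (NA when Ks = 0), `s_sites`, `n_sites`,
#'   `sd` (synonymous differences), `nd` (nonsynonymous differences).
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("aligned CDS lengths differ")
  gc <- .codon_table()
  ca <- .split_codons(cds_a)
  cb <- .split_codons(cds_b)
  aa_a <- unname(gc[ca]); aa_b <- unname(gc[cb])
  internal <- seq_len(length(ca) - 1)
  if (any(aa_a[internal] == "*") || any(aa_b[internal] == "*")) {
    stop("internal stop codon in CDS")
  }
  # drop a trailing stop codon pair if present
  if (aa_a[length(ca)] == "*" || aa_b[length(cb)] == "*") {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  s_a <- sum(vapply(ca, .syn_sites_codon, 0, gc = gc))
  s_b <- sum(vapply(cb, .syn_sites_codon, 0, gc = gc))
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i) .codon_diffs(ca[i], cb[i], gc), c(sd = 0, nd = 0))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  jc <- function(p) {
    if (p >= 0.75) stop("substitution proportion >= 3/4; Jukes-Cantor correction undefined")
    max(-3 / 4 * log(1 - 4 * p / 3), 0)
  }
  ks <- if (S > 0) jc(Sd / S) else NA_real_
  ka <- if (N > 0) jc(Nd / N) else NA_real_
  ratio <- if (!is.na(ks) && ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, ratio = ratio, s_sites = S, n_sites = N, sd = Sd, nd = Nd)
}

#' Ka/Ks for a table of aligned CDS pairs
#'
#' @param pairs data.table with `pair_id`, `cds_a`, `cds_b`.
#' @return data.table: `pair_id`, `ka`, `ks`, `ratio`, `s_sites`, `n_sites`.
#' @export
kaks_table <- function(pairs) {
  pairs <- as.data.table(pairs)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- ng86_kaks(pairs$cds_a[i], pairs$cds_b[i])
    data.table(pair_id = pairs$pair_id[i], ka = r$ka, ks = r$ks, ratio = r$ratio,
               s_sites = r$s_sites, n_sites = r$n_sites)
  })
  rbindlist(res)
}
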