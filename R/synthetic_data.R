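#' Synthetic study generator with planted ground truth
#'
#' Generates every input the pipeline consumes -- a 3-subgenome genome with
#' ordered genes, family genes organized as 1:1:1 triads plus dyads,
#' singletons and planted tandem clusters; TPM matrices with planted bias
#' categories and Dirichlet simplex noise; stress/control pairs with planted
#' induction; aligned CDS pairs with controlled synonymous/nonsynonymous
#' divergence; transcripts with planted miRNA target sites and degradome
#' spikes; and replicate peak sets with a planted reproducible fraction.
#' Every generator is deterministic given the config seed and leaves the
#' caller's RNG untouched.
#'
#' @name synthetic_data
NULL

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions of the wheat family analysis:
#' retention of triad genes at 0.80 (44 triads, 8 dyads, 9 singletons and 8
#' tandem-duplicate extras give 132/165), a bias mixture dominated by the
#' balanced category (0.62) with elevated D-suppression (0.16), four
#' tissues (root, leaf, spikelet, grain) with two replicate samples each,
#' and a centromeric segment C occupying 10% of each chromosome.
#'
#' @param seed integer RNG seed.
#' @param n_triad_groups homoeologous groups forming full 1:1:1 triads.
#' @param n_dyad_groups groups with members on only two subgenomes.
#' @param n_singleton_groups groups with a single member.
#' @param n_tandem_extra extra family genes planted adjacent (rank gap <= 3)
#'   to existing family genes to create tandem clusters.
#' @param genes_per_chromosome annotated genes per chromosome.
#' @param bias_mixture named probabilities over the 7 bias categories
#'   (must sum to 1).
#' @param dirichlet_concentration simplex noise knob; `Inf` = no noise.
#' @param n_replicates samples per tissue.
#' @param low_expression_fraction fraction of triad x tissue cells forced
#'   below the 0.5 summed-TPM filter.
#' @param stress_n_conditions,stress_effect_lfc,stress_induced_fraction
#'   stress design: number of conditions, planted log2 effect size, fraction
#'   of genes induced.
#' @param n_cds_pairs_per_class aligned CDS pairs per substitution class.
#' @param cds_n_codons codons per simulated CDS (default 300, a typical CDS
#'   length; with `cds_n_mutations = 90` the pairwise divergence is ~10%,
#'   enough synonymous events for a stable Jukes-Cantor estimate).
#' @param cds_n_mutations planted substitutions per pair.
#' @param silent_gene_fraction fraction of non-triad family genes left
#'   unexpressed in every tissue.
#' @param mirna_len miRNA length (nt).
#' @param n_transcripts,transcript_len,mirna_site_fraction degradome design.
#' @param peaks_per_mark,peak_shared_fraction,peak_width ChIP replicate
#'   design.
#' @param segment_fractions named fractions (R1, R2a, C, R2b, R3) that
#'   partition each chromosome.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1,
                       n_triad_groups = 44,
                       n_dyad_groups = 8,
                       n_singleton_groups = 9,
                       n_tandem_extra = 8,
                       genes_per_chromosome = 400,
                       bias_mixture = c(balanced = 0.62, `A-dominant` = 0.025,
                                        `B-dominant` = 0.025, `D-dominant` = 0.02,
                                        `A-suppressed` = 0.08, `B-suppressed` = 0.07,
                                        `D-suppressed` = 0.16),
                       dirichlet_concentration = 200,
                       n_replicates = 2,
                       low_expression_fraction = 0.05,
                       stress_n_conditions = 6,
                       stress_effect_lfc = 2.5,
                       stress_induced_fraction = 0.05,
                       n_cds_pairs_per_class = 5,
                       cds_n_codons = 300,
                       cds_n_mutations = 90,
                       silent_gene_fraction = 0.35,
                       mirna_len = 21,
                       n_transcripts = 20,
                       transcript_len = 500,
                       mirna_site_fraction = 0.3,
                       peaks_per_mark = 40,
                       peak_shared_fraction = 0.6,
                       peak_width = 1500,
                       segment_fractions = c(R1 = 0.25, R2a = 0.2, C = 0.1,
                                             R2b = 0.2, R3 = 0.25)) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(cfg$bias_mixture) - 1) < 1e-9,
            setequal(names(cfg$bias_mixture), rownames(bias_archetypes())),
            abs(sum(cfg$segment_fractions) - 1) < 1e-9,
            cfg$genes_per_chromosome > 0, cfg$n_triad_groups > 0)
  structure(cfg, class = "SimConfig")
}

#' Simulate the genome: gene models, family table, homoeolog groups, segments
#'
#' 21 chromosomes (7 groups x subgenomes A/B/D), `genes_per_chromosome`
#' genes each at regular positions. Family genes (triads at the same
#' chromosomal slot on A/B/D, plus dyads, singletons and tandem extras
#' planted at rank gaps <= 3) are interleaved among background genes.
#'
#' @param config [sim_config()].
#' @return list: `genes` (as from [read_gff3()]), `family` (data.table
#'   `gene_id`), `groups` (`gene_id`, `homoeolog_group`), `segments`
#'   (BED-style data.table), `truth` (list with `triads`,
#'   `tandem_clusters`, `retention`).
#' @export
simulate_genome <- function(config) {
  .with_seed(config$seed + 101L, {
    chroms <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
    gpc <- config$genes_per_chromosome
    gene_w <- 3000L; gene_sp <- 5000L
    chrom_len <- gpc * gene_sp

    # family slot indices spread along each chromosome, >= 6 ranks apart so
    # regular family genes never form accidental tandem chains
    n_groups <- config$n_triad_groups + config$n_dyad_groups + config$n_singleton_groups
    per_chrom_groups <- ceiling(n_groups / 7)
    slot_idx <- round(seq(0.06, 0.94, length.out = max(per_chrom_groups, 2)) * gpc)
    # slots must stay > max_gap+2 apart (no accidental tandem chains) and
    # leave room for the planted tandem extras two ranks downstream
    if (slot_idx[1] < 1 || any(diff(slot_idx) < 6) || max(slot_idx) + 2 > gpc) {
      stop("config infeasible: too many family genes for genes_per_chromosome")
    }

    fam <- list()     # gene_id, chrom, slot
    groups <- list()
    truth_triads <- list()
    next_slot <- setNames(rep(1L, 7), as.character(1:7))
    gid <- function(ch, idx) sprintf("SYN%s_%04d", ch, idx)

    assign_member <- function(grp_id, grp_num, subg, slot) {
      ch <- paste0(grp_num, subg)
      id <- gid(ch, slot)
      fam[[length(fam) + 1]] <<- data.table(gene_id = id, chrom = ch, slot = slot)
      groups[[length(groups) + 1]] <<- data.table(gene_id = id, homoeolog_group = grp_id)
      id
    }

    grp_id <- 0L
    for (i in seq_len(config$n_triad_groups)) {
      grp_id <- grp_id + 1L
      gn <- (grp_id - 1L) %% 7L + 1L
      slot <- slot_idx[next_slot[[as.character(gn)]]]
      next_slot[[as.character(gn)]] <- next_slot[[as.character(gn)]] + 1L
      ids <- vapply(c("A", "B", "D"), function(s) assign_member(sprintf("G%03d", grp_id), gn, s, slot), "")
      truth_triads[[i]] <- data.table(group = sprintf("G%03d", grp_id),
                                      a_id = ids[1], b_id = ids[2], d_id = ids[3])
    }
    for (i in seq_len(config$n_dyad_groups)) {
      grp_id <- grp_id + 1L
      gn <- (grp_id - 1L) %% 7L + 1L
      slot <- slot_idx[next_slot[[as.character(gn)]]]
      next_slot[[as.character(gn)]] <- next_slot[[as.character(gn)]] + 1L
      for (s in c("A", "B")) assign_member(sprintf("G%03d", grp_id), gn, s, slot)
    }
    for (i in seq_len(config$n_singleton_groups)) {
      grp_id <- grp_id + 1L
      gn <- (grp_id - 1L) %% 7L + 1L
      slot <- slot_idx[next_slot[[as.character(gn)]]]
      next_slot[[as.character(gn)]] <- next_slot[[as.character(gn)]] + 1L
      assign_member(sprintf("G%03d", grp_id), gn, "D", slot)
    }
    fam <- rbindlist(fam)

    # tandem extras: each planted 2 ranks after a distinct anchor family gene
    anchors <- fam[sample.int(nrow(fam), config$n_tandem_extra)]
    tandem_truth <- list()
    for (i in seq_len(nrow(anchors))) {
      a <- anchors[i]
      slot <- a$slot + 2L
      id <- gid(a$chrom, slot)
      fam <- rbindlist(list(fam, data.table(gene_id = id, chrom = a$chrom, slot = slot)))
      tandem_truth[[i]] <- data.table(chrom = a$chrom,
                                      anchor = a$gene_id, extra = id)
    }
    if (anyDuplicated(fam$gene_id)) stop("config infeasible: family slot collision")

    genes <- rbindlist(lapply(chroms, function(ch) {
      idx <- seq_len(gpc)
      famslots <- fam[chrom == ch, slot]
      data.table(gene_id = gid(ch, idx), chrom = ch,
                 start = (idx - 1L) * gene_sp,
                 end = (idx - 1L) * gene_sp + gene_w,
                 strand = sample(c("+", "-"), gpc, replace = TRUE),
                 exon_count = sample(1:5, gpc, replace = TRUE),
                 rank = idx)
    }))
    genes <- cbind(genes[, !c("rank")], parse_chrom_name(genes$chrom))
    genes[, rank := seq_len(.N), by = chrom]

    segments <- rbindlist(lapply(chroms, function(ch) {
      fr <- config$segment_fractions
      bounds <- round(cumsum(c(0, fr)) * chrom_len)
      data.table(chrom = ch, start = bounds[-length(bounds)],
                 end = bounds[-1], name = names(fr))
    }))

    retention <- 3 * config$n_triad_groups / nrow(fam)
    list(
      genes = genes,
      family = fam[, .(gene_id, chrom)],
      groups = rbindlist(groups),
      segments = segments,
      truth = list(triads = rbindlist(truth_triads),
                   tandem_clusters = rbindlist(tandem_truth),
                   retention = retention)
    )
  })
}

.rdirichlet <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- alpha / sum(alpha)  # degenerate draw guard
  x / sum(x)
}

#' Simulate triad TPM expression with planted bias categories
#'
#' Per triad x tissue a category is drawn from the configured mixture; the
#' relative abundances are a Dirichlet draw centred on the category's
#' archetype (`alpha = concentration * archetype + 0.02`, exact archetype
#' when concentration is infinite); the total TPM is log-normal. A fraction
#' of cells is forced below the summed-TPM filter. Replicate samples share
#' the triad's relative abundances and differ only by a common magnitude
#' factor, so within-triad proportions carry all the simplex signal.
#'
#' @param config [sim_config()].
#' @param triads data.table `group`, `a_id`, `b_id`, `d_id`.
#' @param extra_genes optional character vector of additional (non-triad)
#'   gene ids given independent log-normal expression.
#' @return list: `em` ([ExpressionMatrix][expression_matrix]),
#'   `truth` (data.table `group`, `tissue`, `category`, `below_filter`).
#' @export
simulate_expression <- function(config, triads, extra_genes = character()) {
  .with_seed(config$seed + 202L, {
    tissues <- c("root", "leaf", "spikelet", "grain")
    tclass <- c(root = "root", leaf = "vegetative",
                spikelet = "reproductive", grain = "reproductive")
    arch <- bias_archetypes()
    mix <- config$bias_mixture[rownames(arch)]
    conc <- config$dirichlet_concentration
    nrep <- config$n_replicates
    triads <- as.data.table(triads)

    samples <- data.table(
      sample_id = paste0(rep(tissues, each = nrep), "_r", seq_len(nrep)),
      tissue = rep(tissues, each = nrep),
      stage = "mid",
      condition = "control",
      tissue_class = tclass[rep(tissues, each = nrep)]
    )

    gene_ids <- unique(c(triads$a_id, triads$b_id, triads$d_id, extra_genes))
    vals <- matrix(0, length(gene_ids), nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
    truth <- list()
    for (ti in seq_len(nrow(triads))) {
      tr <- triads[ti]
      for (tis in tissues) {
        category <- sample(names(mix), 1, prob = mix)
        a <- arch[category, ]
        rel <- if (is.infinite(conc)) a else .rdirichlet(conc * a + 0.02)
        below <- runif(1) < config$low_expression_fraction
        total <- if (below) runif(1, 0, 0.4) else 1 + rlnorm(1, log(20), 0.8)
        for (r in seq_len(nrep)) {
          # shared magnitude factor per sample; exact total for planted
          # sub-threshold cells so the 0.5 filter recovers them verbatim
          mag <- if (below) 1 else exp(rnorm(1, 0, 0.1))
          vals[c(tr$a_id, tr$b_id, tr$d_id), paste0(tis, "_r", r)] <- rel * total * mag
        }
        truth[[length(truth) + 1]] <- data.table(group = tr$group, tissue = tis,
                                                 category = category, below_filter = below)
      }
    }
    for (g in extra_genes) {
      silent <- runif(1) < config$silent_gene_fraction
      for (tis in tissues) {
        tpm <- if (silent) runif(1, 0, 0.3) else 1 + rlnorm(1, log(3), 1.2)
        for (r in seq_len(nrep)) {
          vals[g, paste0(tis, "_r", r)] <- tpm * (if (silent) 1 else exp(rnorm(1, 0, 0.1)))
        }
      }
    }
    list(em = expression_matrix(vals, samples), truth = rbindlist(truth))
  })
}

#' Simulate stress/control TPM pairs with planted induction
#'
#' @param config [sim_config()].
#' @param gene_ids genes to simulate.
#' @return list: `data` (data.table `gene_id`, `condition`, `control_tpm`,
#'   `stress_tpm`), `truth` (data.table `gene_id`, `condition`, `induced`).
#' @export
simulate_stress <- function(config, gene_ids) {
  .with_seed(config$seed + 303L, {
    conds <- sprintf("stress%02d", seq_len(config$stress_n_conditions))
    out <- list(); truth <- list()
    for (cond in conds) {
      control <- rlnorm(length(gene_ids), log(5), 1)
      induced <- runif(length(gene_ids)) < config$stress_induced_fraction
      fc <- ifelse(induced, 2^config$stress_effect_lfc, 2^rnorm(length(gene_ids), 0, 0.2))
      # stress chosen so that log2((stress+0.5)/(control+0.5)) = log2(fc) exactly
      stress <- pmax(fc * (control + 0.5) - 0.5, 0)
      out[[cond]] <- data.table(gene_id = gene_ids, condition = cond,
                                control_tpm = control, stress_tpm = stress)
      truth[[cond]] <- data.table(gene_id = gene_ids, condition = cond, induced = induced)
    }
    list(data = rbindlist(out), truth = rbindlist(truth))
  })
}

.codons_no_stop <- function() {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  gc <- .codon_table()
  all_codons[gc[all_codons] != "*"]
}

.random_cds <- function(n_codons) paste(sample(.codons_no_stop(), n_codons, replace = TRUE), collapse = "")

# apply k single-base substitutions of a given class to a CDS;
# class "synonymous"/"nonsynonymous" constrains each change (and touches each
# codon at most once, so planted classes stay pure under pathway counting),
# "any" leaves the substitution process uniform (stop-creating draws redrawn)
.mutate_cds <- function(cds, k, class = c("any", "synonymous", "nonsynonymous")) {
  class <- match.arg(class)
  gc <- .codon_table()
  codons <- .split_codons(cds)
  bases <- c("A", "C", "G", "T")
  touched <- logical(length(codons))
  done <- 0; guard <- 0
  while (done < k && guard < 20000) {
    guard <- guard + 1
    ci <- sample.int(length(codons), 1)
    if (class != "any" && touched[ci]) next
    p <- sample.int(3, 1)
    old <- codons[ci]
    b <- sample(setdiff(bases, substr(old, p, p)), 1)
    mut <- old
    substr(mut, p, p) <- b
    if (gc[[mut]] == "*") next
    syn <- gc[[mut]] == gc[[old]]
    if (class == "synonymous" && !syn) next
    if (class == "nonsynonymous" && syn) next
    codons[ci] <- mut
    touched[ci] <- TRUE
    done <- done + 1
  }
  if (done < k) stop("could not place the requested substitutions")
  paste(codons, collapse = "")
}

#' Simulate aligned CDS pairs with controlled divergence classes
#'
#' Each pair mutates a shared random in-frame ancestor with substitutions
#' restricted to synonymous-only, nonsynonymous-only, or an unconstrained
#' equal-rate process (uniform random substitutions, stop codons avoided).
#'
#' @param config [sim_config()].
#' @return data.table: `pair_id`, `class`, `cds_a`, `cds_b`.
#' @export
simulate_cds_pairs <- function(config) {
  .with_seed(config$seed + 404L, {
    classes <- c("synonymous", "nonsynonymous", "any")
    out <- list()
    for (cl in classes) {
      for (i in seq_len(config$n_cds_pairs_per_class)) {
        anc <- .random_cds(config$cds_n_codons)
        der <- .mutate_cds(anc, config$cds_n_mutations, cl)
        out[[length(out) + 1]] <- data.table(
          pair_id = sprintf("%s_%02d", cl, i), class = cl, cds_a = anc, cds_b = der)
      }
    }
    rbindlist(out)
  })
}

.revcomp_rna_as_dna <- function(x) {
  x <- toupper(gsub("U", "T", x))
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Simulate transcripts, a miRNA and degradome profiles
#'
#' A fraction of transcripts carries a perfect reverse-complement miRNA site
#' at a random position; their degradome profiles place a dominant unique
#' 5'-end spike exactly at the position opposite miRNA position 10, over
#' sparse low background counts.
#'
#' @param config [sim_config()].
#' @return list: `mirna` (sequence), `transcripts` (named character),
#'   `profiles` (named list of integer vectors), `truth` (data.table
#'   `transcript_id`, `has_site`, `site_start`, `cleavage_site`).
#' @export
simulate_degradome <- function(config) {
  .with_seed(config$seed + 505L, {
    bases <- c("A", "C", "G", "T")
    L <- config$mirna_len
    mirna <- paste(sample(bases, L, replace = TRUE), collapse = "")
    site <- .revcomp_rna_as_dna(mirna)
    n <- config$n_transcripts
    len <- config$transcript_len
    has_site <- seq_len(n) <= round(config$mirna_site_fraction * n)
    transcripts <- character(n); names(transcripts) <- sprintf("TX%03d", seq_len(n))
    profiles <- vector("list", n); names(profiles) <- names(transcripts)
    truth <- list()
    for (i in seq_len(n)) {
      tx <- sample(bases, len, replace = TRUE)
      site_start <- NA_integer_; cleave <- NA_integer_
      if (has_site[i]) {
        site_start <- sample.int(len - L + 1, 1) - 1L  # 0-based
        tx[(site_start + 1):(site_start + L)] <- strsplit(site, "")[[1]]
        cleave <- site_start + L - 10L
      }
      transcripts[i] <- paste(tx, collapse = "")
      prof <- integer(len)
      bg_pos <- sample.int(len, round(0.05 * len))
      prof[bg_pos] <- sample(1:3, length(bg_pos), replace = TRUE)
      if (has_site[i]) prof[cleave + 1L] <- 30L  # dominant unique spike
      profiles[[i]] <- prof
      truth[[i]] <- data.table(transcript_id = names(transcripts)[i],
                               has_site = has_site[i],
                               site_start = site_start, cleavage_site = cleave)
    }
    list(mirna = mirna, transcripts = transcripts, profiles = profiles,
         truth = rbindlist(truth))
  })
}

#' Simulate replicate ChIP peak sets with a planted shared fraction
#'
#' Peaks are laid out on disjoint genomic slots so replicate-private peaks
#' can never overlap the other replicate; shared peaks are jittered between
#' replicates while keeping at least 1 bp of overlap. When `target_genes`
#' is supplied, a fraction of the shared peaks is centred inside sampled
#' gene bodies (the rest land in a peripheral coordinate region beyond every
#' gene), planting a known marked-gene set.
#'
#' @param config [sim_config()].
#' @param mark mark label (default `"H3K27me3"`).
#' @param target_genes optional data.table `gene_id`, `chrom`, `start`,
#'   `end`; a `marked_fraction` share of them receives a shared peak in the
#'   gene body.
#' @param marked_fraction fraction of `target_genes` to mark (default 0.3).
#' @return list: `rep1`, `rep2` (peak data.tables), `truth` (data.table of
#'   the credible intervals the overlap step should emit: `chrom`, `start`,
#'   `end`), `marked_genes` (character vector, empty without
#'   `target_genes`).
#' @export
simulate_peaks <- function(config, mark = "H3K27me3", target_genes = NULL,
                           marked_fraction = 0.3) {
  .with_seed(config$seed + 606L, {
    n <- config$peaks_per_mark
    n_shared <- round(config$peak_shared_fraction * n)
    n_private <- n - n_shared
    w <- config$peak_width

    marked <- character()
    gene_peaks <- data.table(chrom = character(), start = integer(), end = integer())
    offset <- 1000L
    if (!is.null(target_genes) && n_shared > 0) {
      tg <- as.data.table(target_genes)
      n_marked <- min(round(marked_fraction * nrow(tg)), n_shared)
      pick <- tg[sample.int(nrow(tg), n_marked)]
      # peak starts inside the gene body; width may run past the gene end,
      # overlap with the body is still guaranteed
      gene_peaks <- pick[, .(chrom, start = start + 10L, end = start + 10L + w)]
      marked <- pick$gene_id
      offset <- as.integer(max(tg$end) + 10 * w)
    }
    n_slots <- n_shared - nrow(gene_peaks) + 2L * n_private
    slot_w <- w * 3L
    chroms <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
    slot <- seq_len(n_slots)
    slot_tab <- data.table(
      chrom = chroms[(slot - 1) %% length(chroms) + 1],
      start = ((slot - 1) %/% length(chroms)) * slot_w + offset
    )[, end := start + w]
    shared <- rbindlist(list(gene_peaks,
                             slot_tab[seq_len(n_shared - nrow(gene_peaks))]))
    priv1 <- slot_tab[n_shared - nrow(gene_peaks) + seq_len(n_private)]
    priv2 <- slot_tab[n_shared - nrow(gene_peaks) + n_private + seq_len(n_private)]

    # |jitter| < width guarantees >= 1 bp overlap with the rep1 copy
    jit <- if (n_shared) sample(seq(-w + 1L, w - 1L), n_shared, replace = TRUE) else integer()
    mark_label <- mark
    with_mark <- function(x) {
      y <- x[, .(chrom, start, end)]
      y[, mark := rep(mark_label, .N)]
      y
    }
    rep1 <- rbindlist(list(with_mark(shared), with_mark(priv1)))
    rep2 <- rbindlist(list(
      with_mark(shared)[, `:=`(start = start + jit, end = end + jit)],
      with_mark(priv2)))
    # truth records the union interval the credible-peak step will emit
    truth <- data.table(chrom = shared$chrom,
                        start = shared$start + pmin(0L, jit),
                        end = shared$end + pmax(0L, jit))
    list(rep1 = rep1, rep2 = rep2, truth = truth, marked_genes = marked)
  })
}

#' Simulate homology hits and domain evidence for the family genes
#'
#' Family genes receive a hit passing all membership thresholds and complete
#' HMM domain evidence; a set of decoy genes receives hits failing at least
#' one threshold or truncated domains, exercising every rejection path.
#'
#' @param config [sim_config()].
#' @param family_ids true family gene ids.
#' @param decoy_ids non-family gene ids to emit failing evidence for.
#' @return list: `hits` (as from [read_hit_table()]), `evidence` (domain
#'   table), `truth` (character vector = `family_ids`).
#' @export
simulate_homology_evidence <- function(config, family_ids, decoy_ids) {
  .with_seed(config$seed + 707L, {
    n <- length(family_ids)
    hits_fam <- data.table(
      query_id = family_ids, subject_id = "REF_PROT_1",
      identity = runif(n, 62, 95), evalue = 10^runif(n, -80, -6),
      coverage = runif(n, 0.55, 1)
    )
    nd <- length(decoy_ids)
    fail_mode <- sample(c("identity", "evalue", "coverage", "domain"), nd, replace = TRUE)
    hits_dec <- data.table(
      query_id = decoy_ids, subject_id = "REF_PROT_1",
      identity = ifelse(fail_mode == "identity", runif(nd, 20, 59), runif(nd, 62, 95)),
      evalue = ifelse(fail_mode == "evalue", 10^runif(nd, -4, -1), 10^runif(nd, -80, -6)),
      coverage = ifelse(fail_mode == "coverage", runif(nd, 0.05, 0.45), runif(nd, 0.55, 1))
    )
    ev_fam <- data.table(protein_id = family_ids, domain_id = "FAMDOM",
                         source = "hmm", evalue = 10^runif(n, -40, -6),
                         status = "complete")
    dec_dom <- decoy_ids[fail_mode == "domain"]
    ev_dec <- data.table(protein_id = dec_dom, domain_id = "FAMDOM",
                         source = "hmm", evalue = 10^runif(length(dec_dom), -40, -6),
                         status = "truncated")
    list(hits = rbindlist(list(hits_fam, hits_dec)),
         evidence = rbindlist(list(ev_fam, ev_dec)),
         truth = family_ids)
  })
}

#' Materialize a full synthetic study on disk
#'
#' Writes every input in the exact formats the readers consume, plus truth
#' TSVs, under `dir`. The seed is recorded in a header file.
#'
#' @param config [sim_config()].
#' @param dir output directory (created).
#' @return invisibly, the list of generated objects.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(config)
  expr <- simulate_expression(config, genome$truth$triads,
                              extra_genes = setdiff(genome$family$gene_id,
                                                    unlist(genome$truth$triads[, .(a_id, b_id, d_id)])))
  stress <- simulate_stress(config, genome$family$gene_id)
  cds <- simulate_cds_pairs(config)
  degradome <- simulate_degradome(config)
  peaks <- simulate_peaks(config,
                          target_genes = genome$genes[gene_id %in% genome$family$gene_id,
                                                      .(gene_id, chrom, start, end)])

  write_gff3(genome$genes, file.path(dir, "genome.gff3"))
  write_tsv(genome$family, file.path(dir, "family.tsv"))
  write_tsv(genome$groups, file.path(dir, "homoeolog_groups.tsv"))
  write_bed(genome$segments, file.path(dir, "segments.bed"))
  tpm <- data.table(gene_id = rownames(expr$em$values))
  tpm <- cbind(tpm, as.data.table(expr$em$values))
  write_tsv(tpm, file.path(dir, "tpm.tsv"))
  write_tsv(expr$em$meta, file.path(dir, "samples.tsv"))
  write_tsv(stress$data, file.path(dir, "stress.tsv"))
  write_tsv(cds, file.path(dir, "cds_pairs.tsv"))
  writeLines(c(">miR_synth", degradome$mirna), file.path(dir, "mirna.fa"))
  writeLines(as.vector(rbind(paste0(">", names(degradome$transcripts)),
                             degradome$transcripts)),
             file.path(dir, "transcripts.fa"))
  prof <- rbindlist(lapply(names(degradome$profiles), function(id) {
    p <- degradome$profiles[[id]]
    data.table(transcript_id = id, pos = which(p > 0), count = p[p > 0])
  }))
  write_tsv(prof, file.path(dir, "degradome.tsv"))
  write_bed(peaks$rep1[, .(chrom, start, end, name = mark)], file.path(dir, "peaks_rep1.bed"))
  write_bed(peaks$rep2[, .(chrom, start, end, name = mark)], file.path(dir, "peaks_rep2.bed"))
  write_tsv(genome$truth$triads, file.path(dir, "truth_triads.tsv"))
  write_tsv(genome$truth$tandem_clusters, file.path(dir, "truth_tandem.tsv"))
  write_tsv(expr$truth, file.path(dir, "truth_bias.tsv"))
  write_tsv(stress$truth, file.path(dir, "truth_stress.tsv"))
  write_tsv(degradome$truth, file.path(dir, "truth_degradome.tsv"))
  write_tsv(peaks$truth, file.path(dir, "truth_peaks.tsv"))
  writeLines(peaks$marked_genes, file.path(dir, "truth_marked_genes.txt"))
  writeLines(sprintf("seed: %d", config$seed), file.path(dir, "SEED"))
  invisible(list(genome = genome, expression = expr, stress = stress,
                 cds = cds, degradome = degradome, peaks = peaks))
}
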