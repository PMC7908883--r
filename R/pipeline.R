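#' End-to-end pipeline orchestration
#'
#' Runs the stages in dependency order over a study directory (as written by
#' [simulate_study()] or assembled from real inputs in the same formats),
#' writing one TSV per stage plus a manifest of every threshold, seed and
#' input checksum. Reruns with identical config are idempotent.
#'
#' @name cli_pipeline
NULL

#' Default pipeline configuration
#'
#' All thresholds default to the study's printed values: hit E-value 1e-5,
#' identity 60, coverage 0.5; expressed TPM 0.5; triad summed-TPM floor 0.5;
#' tandem max gap 3; duplex score cutoff 4.5; k-means k = 10.
#'
#' @param input_dir directory of study inputs.
#' @param seed RNG seed for clustering.
#' @param prefix family naming prefix.
#' @param marks histone marks to process.
#' @return named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(input_dir, seed = 1, prefix = "FAM",
                            marks = "H3K27me3") {
  structure(list(
    input_dir = input_dir, seed = seed, prefix = prefix, marks = marks,
    evalue_max = 1e-5, identity_min = 60, coverage_min = 0.5,
    tpm_threshold = 0.5, triad_min_total = 0.5, tandem_max_gap = 3,
    score_max = 4.5, k = 10, lfc_min = 1
  ), class = "PipelineConfig")
}

.validate_config <- function(cfg) {
  with(cfg, {
    if (evalue_max <= 0) stop("config: evalue_max must be positive")
    if (identity_min < 0 || identity_min > 100) stop("config: identity_min outside [0,100]")
    if (coverage_min < 0 || coverage_min > 1) stop("config: coverage_min outside [0,1]")
    if (tpm_threshold < 0) stop("config: tpm_threshold must be >= 0")
    if (triad_min_total < 0) stop("config: triad_min_total must be >= 0")
    if (tandem_max_gap < 0) stop("config: tandem_max_gap must be >= 0")
    if (score_max < 0) stop("config: score_max must be >= 0")
    if (k < 1) stop("config: k must be >= 1")
  })
  invisible(cfg)
}

.read_fasta_chr <- function(path, dna = TRUE) {
  x <- if (dna) Biostrings::readDNAStringSet(path) else Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Run every pipeline stage over a study directory
#'
#' Stage order: triad detection and bias -> expression calls, clustering and
#' stress -> tandem/segments/Ka-Ks -> miRNA targets -> chromatin marks.
#' Each stage writes its TSV contract under `out_dir`; a `manifest.yaml`
#' records thresholds, seed, package version, input checksums and per-stage
#' in/out counts; `stage_status.tsv` tracks completion so partial results
#' are preserved on failure.
#'
#' @param config [pipeline_config()].
#' @param out_dir results directory (created).
#' @return invisibly, named list of per-stage results.
#' @export
run_all <- function(config, out_dir) {
  .validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ind <- config$input_dir
  need <- c("genome.gff3", "family.tsv", "homoeolog_groups.tsv", "segments.bed",
            "tpm.tsv", "samples.tsv", "stress.tsv", "cds_pairs.tsv",
            "mirna.fa", "transcripts.fa", "degradome.tsv",
            "peaks_rep1.bed", "peaks_rep2.bed")
  missing <- need[!file.exists(file.path(ind, need))]
  if (length(missing)) stop("missing pipeline input(s): ", paste(missing, collapse = ", "))

  status <- data.table(stage = character(), status = character())
  log_stage <- function(stage, st) {
    status <<- rbindlist(list(status, data.table(stage = stage, status = st)))
    write_tsv(status, file.path(out_dir, "stage_status.tsv"))
  }
  counts <- list()
  results <- list()

  run_stage <- function(stage, fn) {
    log_stage(stage, "running")
    res <- tryCatch(fn(), error = function(e) {
      log_stage(stage, paste("failed:", conditionMessage(e)))
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
    })
    log_stage(stage, "ok")
    res
  }

  genes <- read_gff3(file.path(ind, "genome.gff3"))
  family <- fread(file.path(ind, "family.tsv"))
  groups <- fread(file.path(ind, "homoeolog_groups.tsv"))
  em <- read_tpm_matrix(file.path(ind, "tpm.tsv"), file.path(ind, "samples.tsv"))
  fam_genes <- genes[gene_id %in% family$gene_id]

  results$triads <- run_stage("triads", function() {
    tri <- detect_triads(fam_genes, groups)
    write_tsv(tri$triads, file.path(out_dir, "triads.tsv"))
    write_tsv(tri$non_triads, file.path(out_dir, "non_triads.tsv"))
    counts$triads <<- list(groups_in = length(unique(groups$homoeolog_group)),
                           triads_out = nrow(tri$triads))
    tri
  })
  results$bias <- run_stage("bias", function() {
    calls <- classify_triads(results$triads$triads, em,
                             min_total = config$triad_min_total)
    write_tsv(calls, file.path(out_dir, "bias_calls.tsv"))
    kept <- calls[filtered == FALSE]
    tern <- cbind(kept[, .(group, tissue)],
                  ternary_coordinates(as.matrix(kept[, .(rA, rB, rD)])))
    write_tsv(tern, file.path(out_dir, "ternary_coordinates.tsv"))
    summ <- bias_summary(calls)
    write_tsv(summ, file.path(out_dir, "bias_summary.tsv"))
    ret <- triad_retention_rate(nrow(family), nrow(results$triads$triads))
    counts$bias <<- list(calls = nrow(calls), filtered = sum(calls$filtered),
                         retention = ret$fraction)
    list(calls = calls, summary = summ, retention = ret)
  })
  results$express <- run_stage("express", function() {
    fam_em <- expression_matrix(em$values[intersect(rownames(em$values), family$gene_id), ,
                                          drop = FALSE], em$meta)
    calls <- call_expressed(fam_em, threshold = config$tpm_threshold)
    write_tsv(calls, file.path(out_dir, "expressed_calls.tsv"))
    k_use <- min(config$k, nrow(fam_em$values))
    clus <- cluster_expression(fam_em, k = k_use, seed = config$seed)
    write_tsv(clus$assignments, file.path(out_dir, "clusters.tsv"))
    counts$express <<- list(genes = nrow(calls), expressed = sum(calls$expressed), k = k_use)
    list(calls = calls, clusters = clus)
  })
  results$stress <- run_stage("stress", function() {
    sd_ <- fread(file.path(ind, "stress.tsv"))
    sd_[, lfc := stress_log_ratio(stress_tpm, control_tpm)]
    ind_res <- flag_induced(sd_[, .(gene_id, condition, lfc)], lfc_min = config$lfc_min)
    write_tsv(ind_res$calls, file.path(out_dir, "stress_lfc.tsv"))
    write_tsv(ind_res$summary, file.path(out_dir, "stress_induced.tsv"))
    counts$stress <<- list(pairs = nrow(sd_), induced_calls = sum(ind_res$calls$induced))
    ind_res
  })
  results$tandem <- run_stage("tandem", function() {
    cl <- find_tandem_clusters(genes[gene_id %in% family$gene_id],
                               max_gap = config$tandem_max_gap)
    write_tsv(cl, file.path(out_dir, "tandem_clusters.tsv"))
    counts$tandem <<- list(clusters = length(unique(cl$cluster_id)))
    cl
  })
  results$segments <- run_stage("segments", function() {
    segs <- read_bed(file.path(ind, "segments.bed"))
    fam_seg <- segment_assign(fam_genes, segs)
    all_seg <- segment_assign(genes, segs)
    obs <- table(factor(fam_seg$segment, levels = unique(segs$name)))
    props <- prop.table(table(factor(all_seg$segment, levels = unique(segs$name))))
    enr <- segment_enrichment(setNames(as.integer(obs), names(obs)),
                              n = nrow(fam_seg),
                              genome_props = setNames(as.numeric(props), names(props)))
    write_tsv(fam_seg, file.path(out_dir, "segment_assignments.tsv"))
    write_tsv(enr, file.path(out_dir, "segment_enrichment.tsv"))
    enr
  })
  results$kaks <- run_stage("kaks", function() {
    pairs <- fread(file.path(ind, "cds_pairs.tsv"))
    kk <- kaks_table(pairs)
    write_tsv(kk, file.path(out_dir, "kaks.tsv"))
    kk
  })
  results$mirtarget <- run_stage("mirtarget", function() {
    mirna <- .read_fasta_chr(file.path(ind, "mirna.fa"))[[1]]
    tx <- .read_fasta_chr(file.path(ind, "transcripts.fa"))
    prof_tab <- fread(file.path(ind, "degradome.tsv"))
    profiles <- lapply(setNames(names(tx), names(tx)), function(id) {
      p <- integer(nchar(tx[[id]]))
      rows <- prof_tab[transcript_id == id]
      p[rows$pos] <- rows$count
      p
    })
    tg <- predict_targets(mirna, tx, profiles, score_max = config$score_max)
    write_tsv(tg, file.path(out_dir, "mirna_targets.tsv"))
    counts$mirtarget <<- list(transcripts = length(tx), targets = nrow(tg))
    tg
  })
  results$chip <- run_stage("chip", function() {
    r1 <- read_bed(file.path(ind, "peaks_rep1.bed"))
    r2 <- read_bed(file.path(ind, "peaks_rep2.bed"))
    per_mark <- lapply(config$marks, function(mk) {
      credible_peaks(r1[name == mk][, mark := mk], r2[name == mk][, mark := mk])
    })
    cred <- rbindlist(per_mark)
    write_bed(cred[, .(chrom, start, end, name = mark, strand = ".")],
              file.path(out_dir, "credible_peaks.bed"))
    asg <- assign_marks(cred, fam_genes)
    tab <- mark_expression_table(asg, results$express$calls)
    write_tsv(asg, file.path(out_dir, "mark_assignments.tsv"))
    write_tsv(tab, file.path(out_dir, "mark_expression_table.tsv"))
    counts$chip <<- list(credible = nrow(cred))
    list(credible = cred, assignments = asg, table = tab)
  })

  manifest <- list(
    package = as.character(utils::packageVersion("polyfam")),
    seed = config$seed,
    thresholds = config[setdiff(names(config), c("input_dir"))],
    inputs = as.list(tools::md5sum(file.path(ind, need))),
    counts = counts
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}
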