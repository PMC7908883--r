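#' Replicate-credible ChIP-seq peaks and gene-body mark assignment
#'
#' A peak is credible when it overlaps a peak of the other biological
#' replicate by at least 1 bp; the emitted credible interval is the union of
#' the connected overlapping replicate peaks. A gene is a target of a mark
#' when any credible peak overlaps its gene body (full genomic span,
#' strand-agnostic).
#'
#' @name chromatin_marks
NULL

.as_iranges <- function(x) {
  # internal 0-based half-open -> IRanges 1-based closed
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Derive credible peaks from two biological replicates
#'
#' @param rep1,rep2 data.tables of peaks: `chrom`, `start`, `end`, `mark`
#'   (single mark per call).
#' @param min_overlap minimum cross-replicate overlap in bp (default 1).
#' @param emit `"union"` (default) or `"intersection"` of the overlapping
#'   replicate peaks.
#' @return data.table: `chrom`, `start`, `end`, `mark`; zero rows when no
#'   peak reproduces.
#' @export
credible_peaks <- function(rep1, rep2, min_overlap = 1, emit = c("union", "intersection")) {
  emit <- match.arg(emit)
  rep1 <- validate_intervals(as.data.table(rep1))
  rep2 <- validate_intervals(as.data.table(rep2))
  marks <- unique(c(rep1$mark, rep2$mark))
  marks <- marks[!is.na(marks)]
  if (length(marks) > 1) stop("mismatched mark labels across replicates: ",
                              paste(marks, collapse = ", "))
  mk <- if (length(marks)) marks else NA_character_
  out <- list()
  for (ch in union(rep1$chrom, rep2$chrom)) {
    r1 <- rep1[chrom == ch]; r2 <- rep2[chrom == ch]
    if (!nrow(r1) || !nrow(r2)) next
    ov <- IRanges::findOverlaps(.as_iranges(r1), .as_iranges(r2),
                                minoverlap = min_overlap)
    if (!length(ov)) next
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    # union-find over the bipartite overlap graph
    parent <- seq_len(nrow(r1) + nrow(r2))
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_along(q)) {
      a <- find(q[k]); b <- find(s[k] + nrow(r1))
      if (a != b) parent[b] <- a
    }
    roots1 <- vapply(q, find, 0L)
    comp_of <- split(seq_along(q), roots1)
    for (comp in comp_of) {
      i1 <- unique(q[comp]); i2 <- unique(s[comp])
      if (emit == "union") {
        st <- min(r1$start[i1], r2$start[i2])
        en <- max(r1$end[i1], r2$end[i2])
      } else {
        st <- max(min(r1$start[i1]), min(r2$start[i2]))
        en <- min(max(r1$end[i1]), max(r2$end[i2]))
      }
      out[[length(out) + 1]] <- data.table(chrom = ch, start = st, end = en, mark = mk)
    }
  }
  if (!length(out)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      mark = character()))
  }
  res <- rbindlist(out)
  setorder(res, chrom, start)
  res[]
}

#' Assign histone marks to genes by gene-body overlap
#'
#' @param peaks credible peaks (`chrom`, `start`, `end`, `mark`), possibly
#'   several marks concatenated.
#' @param genes gene models (`gene_id`, `chrom`, `start`, `end`).
#' @return data.table: `gene_id` x `mark` with `has_mark` (every gene x mark
#'   combination present).
#' @export
assign_marks <- function(peaks, genes) {
  peaks <- as.data.table(peaks)
  genes <- as.data.table(genes)
  marks <- sort(unique(peaks$mark))
  grid <- data.table(gene_id = rep(genes$gene_id, each = max(length(marks), 1)),
                     mark = rep(marks, times = nrow(genes)))
  if (!length(marks)) return(data.table(gene_id = character(), mark = character(),
                                        has_mark = logical()))
  grid[, has_mark := FALSE]
  for (mk in marks) {
    pk <- peaks[mark == mk]
    hit_ids <- character()
    for (ch in unique(pk$chrom)) {
      gch <- genes[chrom == ch]
      if (!nrow(gch)) next
      ov <- IRanges::findOverlaps(.as_iranges(gch), .as_iranges(pk[chrom == ch]))
      hit_ids <- c(hit_ids, gch$gene_id[unique(S4Vectors::queryHits(ov))])
    }
    grid[mark == mk & gene_id %in% hit_ids, has_mark := TRUE]
  }
  grid[]
}

#' Cross-tabulate mark presence with expression status
#'
#' @param assignments data.table from [assign_marks()].
#' @param expression_calls data.table from [call_expressed()] (`gene_id`,
#'   `expressed`) covering every assigned gene.
#' @return data.table per mark: counts `expressed_marked`,
#'   `expressed_unmarked`, `nonexpressed_marked`, `nonexpressed_unmarked`
#'   and fractions `frac_marked_expressed`, `frac_marked_nonexpressed`.
#' @export
mark_expression_table <- function(assignments, expression_calls) {
  a <- as.data.table(assignments)
  e <- as.data.table(expression_calls)
  missing <- setdiff(unique(a$gene_id), e$gene_id)
  if (length(missing)) stop("gene without expression call: ", missing[1])
  m <- merge(a, e[, .(gene_id, expressed)], by = "gene_id")
  out <- m[, .(
    expressed_marked = sum(expressed & has_mark),
    expressed_unmarked = sum(expressed & !has_mark),
    nonexpressed_marked = sum(!expressed & has_mark),
    nonexpressed_unmarked = sum(!expressed & !has_mark)
  ), by = mark]
  out[, frac_marked_expressed :=
        ifelse(expressed_marked + expressed_unmarked > 0,
               expressed_marked / (expressed_marked + expressed_unmarked), NA_real_)]
  out[, frac_marked_nonexpressed :=
        ifelse(nonexpressed_marked + nonexpressed_unmarked > 0,
               nonexpressed_marked / (nonexpressed_marked + nonexpressed_unmarked), NA_real_)]
  setorder(out, mark)
  out[]
}
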