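#' Readers and writers for the formats the pipeline touches
#'
#' All coordinates are held internally as 0-based half-open intervals
#' (`start` inclusive, `end` exclusive). GFF3 input (1-based closed) is
#' converted once at the boundary; BED input is already in the internal
#' convention and is taken verbatim. Strand is carried but ignored by all
#' overlap logic.
#'
#' @name core_io
NULL

#' Validate a table of genomic intervals
#'
#' @param x data.table with at least `chrom`, `start`, `end` (0-based
#'   half-open). A `strand` column, if absent, is added as `"."`.
#' @return the validated data.table (invisibly modified by reference only to
#'   add a missing strand column).
#' @export
validate_intervals <- function(x) {
  x <- as.data.table(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (!"strand" %in% names(x)) x[, strand := "."]
  if (nrow(x)) {
    if (any(is.na(x$chrom) | !nzchar(x$chrom))) stop("interval with empty chrom")
    if (any(!is.finite(x$start)) || any(!is.finite(x$end))) stop("non-finite interval coordinate")
    bad <- which(x$end <= x$start)
    if (length(bad)) {
      stop(sprintf("invalid interval (end <= start) at row %d: %s:%d-%d",
                   bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
    }
    if (!all(x$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  }
  x[]
}

#' Parse subgenome and homoeologous group from chromosome names
#'
#' Wheat-style names such as `"4A"` carry the homoeologous group number and
#' the subgenome letter. The pattern must have two capture groups: group
#' number, then subgenome letter.
#'
#' @param chrom character vector of chromosome names.
#' @param pattern regex with two capture groups; default matches `"<digits><A|B|D>"`.
#' @return data.table with columns `group` (integer, NA if unmatched) and
#'   `subgenome` (character, NA if unmatched).
#' @export
parse_chrom_name <- function(chrom, pattern = "^([0-9]+)([ABD])$") {
  m <- regmatches(chrom, regexec(pattern, chrom))
  grp <- vapply(m, function(p) if (length(p) == 3) as.integer(p[2]) else NA_integer_, integer(1))
  sub <- vapply(m, function(p) if (length(p) == 3) p[3] else NA_character_, character(1))
  data.table(group = grp, subgenome = sub)
}

#' Read gene models from a GFF3 file
#'
#' Returns one row per `gene` feature with coordinates converted to the
#' internal 0-based half-open convention, the exon count of its most
#' exon-rich mRNA, and a per-chromosome genome-order rank (1 = leftmost
#' gene start on that chromosome).
#'
#' @param path GFF3 file.
#' @param chrom_pattern passed to [parse_chrom_name()].
#' @return data.table: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `exon_count`, `group`, `subgenome`, `rank`, sorted by (chrom, start).
#' @export
read_gff3 <- function(path, chrom_pattern = "^([0-9]+)([ABD])$") {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.table(gene_id = character(), chrom = character(), start = integer(),
                      end = integer(), strand = character(), exon_count = integer(),
                      group = integer(), subgenome = character(), rank = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9)) {
    i <- which(nf != 9)[1]
    stop(sprintf("GFF3 parse error at line %d: expected 9 tab-separated fields, found %d",
                 lineno[i], nf[i]))
  }
  gff <- data.table(
    lineno = lineno,
    chrom  = vapply(parts, `[`, "", 1L),
    type   = vapply(parts, `[`, "", 3L),
    start1 = suppressWarnings(as.numeric(vapply(parts, `[`, "", 4L))),
    end1   = suppressWarnings(as.numeric(vapply(parts, `[`, "", 5L))),
    strand = vapply(parts, `[`, "", 7L),
    attr   = vapply(parts, `[`, "", 9L)
  )
  bad <- which(is.na(gff$start1) | is.na(gff$end1))
  if (length(bad)) {
    stop(sprintf("GFF3 parse error at line %d: non-numeric start/end", gff$lineno[bad[1]]))
  }
  bad <- which(gff$end1 < gff$start1)
  if (length(bad)) {
    stop(sprintf("GFF3 parse error at line %d: end < start", gff$lineno[bad[1]]))
  }
  attr_field <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attr))
    vapply(m, function(p) if (length(p) == 2) p[2] else NA_character_, character(1))
  }

  genes <- gff[type == "gene"]
  genes[, gene_id := attr_field(attr, "ID")]
  miss <- which(is.na(genes$gene_id))
  if (length(miss)) {
    for (i in miss) warning(sprintf("GFF3 line %d: gene record without ID skipped", genes$lineno[i]))
    genes <- genes[!is.na(gene_id)]
  }

  mrna <- gff[type == "mRNA"]
  mrna_id <- attr_field(mrna$attr, "ID")
  mrna_parent <- attr_field(mrna$attr, "Parent")
  exons <- gff[type == "exon"]
  exon_parent <- attr_field(exons$attr, "Parent")
  # exons may list several parents (shared exons): count each
  exon_parent <- unlist(strsplit(exon_parent[!is.na(exon_parent)], ",", fixed = TRUE))
  exons_per_mrna <- table(exon_parent)
  count_for_gene <- function(gid) {
    tx <- mrna_id[!is.na(mrna_parent) & mrna_parent == gid]
    if (!length(tx)) return(0L)
    as.integer(max(c(0L, exons_per_mrna[tx]), na.rm = TRUE))
  }
  genes[, exon_count := vapply(gene_id, count_for_gene, integer(1))]

  out <- genes[, .(gene_id, chrom, start = as.integer(start1 - 1), end = as.integer(end1),
                   strand, exon_count)]
  out <- cbind(out, parse_chrom_name(out$chrom, chrom_pattern))
  setorder(out, chrom, start, gene_id)
  out[, rank := seq_len(.N), by = chrom]
  out[]
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3()] for gene records: internal 0-based half-open
#' coordinates are converted back to 1-based closed. Each gene is emitted
#' with one mRNA child carrying `exon_count` exons tiled across its span.
#'
#' @param genes data.table as returned by [read_gff3()] (exon_count optional).
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  genes <- as.data.table(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    s1 <- g$start + 1L; e1 <- g$end
    str <- if (!is.null(g$strand)) g$strand else "+"
    writeLines(sprintf("%s\tpolyfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, s1, e1, str, g$gene_id), con)
    nex <- if (!is.null(g$exon_count) && !is.na(g$exon_count)) max(1L, g$exon_count) else 1L
    mid <- paste0(g$gene_id, ".1")
    writeLines(sprintf("%s\tpolyfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, s1, e1, str, mid, g$gene_id), con)
    # tile exons over the span; coordinates are placeholders, only the count matters
    cuts <- floor(seq(s1, e1 + 1L, length.out = nex + 1L))
    for (k in seq_len(nex)) {
      ex_s <- cuts[k]; ex_e <- max(ex_s, cuts[k + 1L] - 1L)
      writeLines(sprintf("%s\tpolyfam\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                         g$chrom, ex_s, ex_e, str, mid, k, mid), con)
    }
  }
  invisible(path)
}

#' Read a blast-style tabular homology hit table
#'
#' Expects the standard 12 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) plus a 13th `qlen`
#' column, or 12 columns with query lengths supplied through `qlen_table`.
#' Coverage is the aligned query span divided by the query length.
#'
#' @param path hit TSV (no header).
#' @param qlen_table optional data.frame `query_id`, `qlen` when the file has
#'   only 12 columns.
#' @return data.table: `query_id`, `subject_id`, `identity` (percent),
#'   `evalue`, `coverage` (fraction of query length).
#' @export
read_hit_table <- function(path, qlen_table = NULL) {
  empty <- data.table(query_id = character(), subject_id = character(),
                      identity = numeric(), evalue = numeric(), coverage = numeric())
  if (file.size(path) == 0) return(empty)
  h <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (!nrow(h)) return(empty)
  if (ncol(h) == 13) {
    setnames(h, c("query_id", "subject_id", "identity", "len", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore", "qlen"))
  } else if (ncol(h) == 12) {
    if (is.null(qlen_table)) stop("12-column hit table requires a qlen_table sidecar")
    setnames(h, c("query_id", "subject_id", "identity", "len", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore"))
    ql <- as.data.table(qlen_table)
    h <- merge(h, ql[, .(query_id, qlen = as.character(qlen))], by = "query_id",
               all.x = TRUE, sort = FALSE)
    if (anyNA(h$qlen)) stop("query missing from qlen_table: ", h$query_id[is.na(h$qlen)][1])
  } else {
    stop("hit table must have 12 or 13 tab-separated columns, found ", ncol(h))
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(h[[col]]))
    if (anyNA(v)) stop(sprintf("non-numeric %s in hit table: '%s'", what, h[[col]][is.na(v)][1]))
    v
  }
  out <- data.table(
    query_id = h$query_id, subject_id = h$subject_id,
    identity = num("identity", "identity"), evalue = num("evalue", "e-value"),
    qstart = num("qstart", "qstart"), qend = num("qend", "qend"), qlen = num("qlen", "qlen")
  )
  out[, coverage := (abs(qend - qstart) + 1) / qlen]
  out[, c("qstart", "qend", "qlen") := NULL]
  out[]
}

#' Read a TPM expression matrix with sample metadata
#'
#' @param path TSV whose first column is the gene id and remaining header
#'   columns are sample ids.
#' @param meta_path TSV with columns `sample_id`, `tissue`, `stage`,
#'   `condition`, `tissue_class`; every matrix sample must be present.
#' @return object of class `ExpressionMatrix`: list with `values` (numeric
#'   matrix genes x samples), `gene_ids`, `sample_ids`, `meta` (data.table).
#' @export
read_tpm_matrix <- function(path, meta_path) {
  m <- fread(path, sep = "\t", header = TRUE)
  gene_ids <- as.character(m[[1]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id in TPM matrix: ", gene_ids[duplicated(gene_ids)][1])
  }
  vals <- as.matrix(m[, -1, with = FALSE])
  mode(vals) <- "numeric"
  rownames(vals) <- gene_ids
  meta <- fread(meta_path, sep = "\t", header = TRUE)
  expression_matrix(vals, meta)
}

#' Construct and validate an ExpressionMatrix
#'
#' @param values numeric matrix, rows = genes (rownames), cols = samples
#'   (colnames), TPM units.
#' @param meta data.frame with `sample_id`, `tissue`, `stage`, `condition`,
#'   `tissue_class` covering every column of `values`.
#' @return `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, meta) {
  meta <- as.data.table(meta)
  req <- c("sample_id", "tissue", "stage", "condition", "tissue_class")
  if (!all(req %in% names(meta))) {
    stop("sample metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values need gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("non-finite TPM value")
  if (any(values < 0)) stop("negative TPM value: ", min(values))
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing)) stop("sample absent from metadata: ", missing[1])
  meta <- meta[match(colnames(values), sample_id)]
  structure(list(values = values, gene_ids = rownames(values),
                 sample_ids = colnames(values), meta = meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d tissues)\n",
              nrow(x$values), ncol(x$values), length(unique(x$meta$tissue))))
  invisible(x)
}

#' Read a BED3+ file of genomic intervals
#'
#' BED coordinates are already 0-based half-open and are kept verbatim.
#' Column 4 (name) and column 6 (strand) are used when present.
#'
#' @param path BED file.
#' @return data.table: `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      name = character(), strand = character())
  if (file.size(path) == 0) return(empty)
  b <- fread(path, header = FALSE, sep = "\t")
  if (ncol(b) < 3) stop("BED file needs at least 3 columns")
  out <- data.table(chrom = as.character(b[[1]]),
                    start = as.integer(b[[2]]), end = as.integer(b[[3]]),
                    name = if (ncol(b) >= 4) as.character(b[[4]]) else NA_character_,
                    strand = if (ncol(b) >= 6) as.character(b[[6]]) else ".")
  validate_intervals(out)
}

#' Write records as a TSV (round-trip stable)
#'
#' @param records data.frame.
#' @param path output path.
#' @export
write_tsv <- function(records, path) {
  fwrite(as.data.table(records), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write intervals as BED
#'
#' @param intervals data.table with `chrom`, `start`, `end` and optionally
#'   `name`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  x <- validate_intervals(intervals)
  cols <- data.table(x$chrom, x$start, x$end)
  if (!is.null(x$name)) {
    cols <- cbind(cols, x$name, 0L, x$strand)
  }
  fwrite(cols, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
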