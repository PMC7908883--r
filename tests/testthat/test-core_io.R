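test_that("GFF3 genes convert to 0-based half-open with exon counts and ranks", {
  gff <- c(
    "##gff-version 3",
    "4A\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "4A\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g1.1;Parent=g1",
    "4A\tsrc\texon\t1\t30\t.\t+\t.\tID=e1;Parent=g1.1",
    "4A\tsrc\texon\t40\t60\t.\t+\t.\tID=e2;Parent=g1.1",
    "4A\tsrc\texon\t70\t100\t.\t+\t.\tID=e3;Parent=g1.1",
    "4A\tsrc\tgene\t501\t900\t.\t-\t.\tID=g2",
    "1B\tsrc\tgene\t51\t80\t.\t+\t.\tID=g3"
  )
  f <- withr::local_tempfile(lines = gff, fileext = ".gff3")
  g <- read_gff3(f)
  g1 <- g[g$gene_id == "g1"]
  expect_equal(g1$start, 0L)
  expect_equal(g1$end, 100L)
  expect_equal(g1$exon_count, 3L)
  expect_equal(g[g$chrom == "4A"][order(start)]$rank, c(1L, 2L))
  expect_equal(g1$group, 4L)
  expect_equal(g1$subgenome, "A")
  # interval length is end - start
  expect_equal(g1$end - g1$start, 100L)
})

test_that("malformed GFF3 lines are rejected with their line number", {
  f <- withr::local_tempfile(
    lines = c("1A\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
              "1A\tsrc\tgene\t5\t50"),
    fileext = ".gff3")
  expect_error(read_gff3(f), "line 2")
  f2 <- withr::local_tempfile(
    lines = "1A\tsrc\tgene\tONE\t100\t.\t+\t.\tID=g1", fileext = ".gff3")
  expect_error(read_gff3(f2), "non-numeric")
})

test_that("gene records without an ID are skipped with a warning", {
  f <- withr::local_tempfile(
    lines = c("1A\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
              "1A\tsrc\tgene\t200\t300\t.\t+\t.\tNote=anon"),
    fileext = ".gff3")
  expect_warning(g <- read_gff3(f), "without ID")
  expect_equal(g$gene_id, "g1")
})

test_that("GFF3 write/read round trip is the identity on gene records", {
  sim <- simulate_genome(sim_config(seed = 3, n_triad_groups = 4,
                                    n_dyad_groups = 1, n_singleton_groups = 1,
                                    n_tandem_extra = 1,
                                    genes_per_chromosome = 30))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$genes, f)
  back <- read_gff3(f)
  cols <- c("gene_id", "chrom", "start", "end", "strand", "exon_count", "rank")
  orig <- data.table::setorder(data.table::copy(sim$genes), chrom, start, gene_id)
  expect_equal(as.data.frame(back[, cols, with = FALSE]),
               as.data.frame(orig[, cols, with = FALSE]))
})

test_that("GFF3 reader coordinates agree with rtracklayer", {
  skip_if_not_installed("rtracklayer")
  sim <- simulate_genome(sim_config(seed = 4, n_triad_groups = 4,
                                    n_dyad_groups = 1, n_singleton_groups = 1,
                                    n_tandem_extra = 1,
                                    genes_per_chromosome = 30))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$genes[chrom %in% c("1A", "2B")], f)
  mine <- read_gff3(f)
  ext <- rtracklayer::import(f)
  ext <- ext[ext$type == "gene"]
  ext <- ext[match(mine$gene_id, ext$ID)]
  expect_equal(mine$start, BiocGenerics::start(ext) - 1L)
  expect_equal(mine$end, BiocGenerics::end(ext))
})

test_that("hit tables parse numerics and compute query coverage", {
  row <- paste(c("q1", "s1", "61.5", "50", "10", "0", "1", "50", "5", "54",
                 "2e-30", "180", "100"), collapse = "\t")
  f <- withr::local_tempfile(lines = row, fileext = ".tsv")
  h <- read_hit_table(f)
  expect_equal(h$identity, 61.5)
  expect_equal(h$evalue, 2e-30)
  expect_equal(h$coverage, 0.5)  # span 1..50 of length 100

  empty <- withr::local_tempfile(lines = character(), fileext = ".tsv")
  expect_equal(nrow(read_hit_table(empty)), 0L)

  bad <- sub("2e-30", "abc", row)
  fb <- withr::local_tempfile(lines = bad, fileext = ".tsv")
  expect_error(read_hit_table(fb), "non-numeric e-value")
})

test_that("TPM matrices validate values and sample metadata", {
  mat <- withr::local_tempfile(
    lines = c("gene_id\ts1\ts2\ts3", "g1\t0\t1.5\t2", "g2\t3\t0\t0.1"),
    fileext = ".tsv")
  meta <- withr::local_tempfile(
    lines = c("sample_id\ttissue\tstage\tcondition\ttissue_class",
              "s1\troot\te\tc\troot", "s2\tleaf\te\tc\tvegetative",
              "s3\tgrain\te\tc\treproductive"),
    fileext = ".tsv")
  em <- read_tpm_matrix(mat, meta)
  expect_equal(dim(em$values), c(2L, 3L))

  neg <- withr::local_tempfile(
    lines = c("gene_id\ts1\ts2\ts3", "g1\t-1\t0\t0"), fileext = ".tsv")
  expect_error(read_tpm_matrix(neg, meta), "negative TPM")

  dup <- withr::local_tempfile(
    lines = c("gene_id\ts1\ts2\ts3", "g1\t0\t0\t0", "g1\t1\t1\t1"),
    fileext = ".tsv")
  expect_error(read_tpm_matrix(dup, meta), "duplicate gene id")

  meta2 <- withr::local_tempfile(
    lines = c("sample_id\ttissue\tstage\tcondition\ttissue_class",
              "s1\troot\te\tc\troot", "s2\tleaf\te\tc\tvegetative"),
    fileext = ".tsv")
  expect_error(read_tpm_matrix(mat, meta2), "s3")
})

test_that("BED intervals are read verbatim, validated and round-trip stable", {
  f <- withr::local_tempfile(lines = "1A\t100\t200", fileext = ".bed")
  b <- read_bed(f)
  expect_equal(b$start, 100L)
  expect_equal(b$end, 200L)

  bad <- withr::local_tempfile(lines = "1A\t200\t100", fileext = ".bed")
  expect_error(read_bed(bad), "end <= start")

  x <- data.table::data.table(chrom = c("1A", "2B"), start = c(5L, 0L),
                              end = c(10L, 3L), name = c("p1", "p2"),
                              strand = c("+", "."))
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, out)
  back <- read_bed(out)
  expect_equal(as.data.frame(back[, .(chrom, start, end, name, strand)]),
               as.data.frame(x))
})

test_that("TSV writer round trips tables", {
  x <- data.table::data.table(id = c("a", "b"), v = c(1.5, -2), n = c(1L, 2L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(x, f)
  back <- data.table::fread(f)
  expect_equal(as.data.frame(back), as.data.frame(x))
})
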