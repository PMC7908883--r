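# reverse complement of an RNA/DNA string, returned as RNA
revcomp_rna <- function(x) {
  x <- chartr("Tt", "Uu", toupper(x))
  paste(rev(chartr("ACGU", "UGCA", strsplit(x, "")[[1]])), collapse = "")
}

test_that("duplex penalties follow the position-weighted scheme", {
  mir <- "UGAUUGAGCCGCGCCAAUAUC"  # 21 nt
  perfect <- revcomp_rna(mir)
  expect_equal(score_duplex(mir, perfect)$score, 0)

  # G:U at miRNA position 5 (core): 0.5 x 2
  mir5 <- mir
  substr(mir5, 5, 5) <- "G"
  w <- revcomp_rna(mir)   # target still complements the original U at pos 5 -> G:A mismatch?
  # build the wobble explicitly: miRNA G faces target U
  target <- strsplit(perfect, "")[[1]]
  target[21 - 5 + 1] <- "U"  # faces miRNA position 5 ("U" -> set miRNA base G)
  mirg <- mir
  substr(mirg, 5, 5) <- "G"
  sc <- score_duplex(mirg, paste(target, collapse = ""))
  expect_equal(sc$score, 1.0)
  expect_equal(sc$states[5], "GU")

  # single mismatch at position 20 (outside the 2-13 core): penalty 1
  t2 <- strsplit(perfect, "")[[1]]
  t2[21 - 20 + 1] <- "C"  # miRNA pos 20 is "A"; A:C is a mismatch
  sc2 <- score_duplex(mir, paste(t2, collapse = ""))
  expect_equal(sc2$score, 1.0)

  expect_error(score_duplex("ANU", "AXU"), "invalid")
})

test_that("combined penalties add position by position", {
  mir <- "UGAUUGAGCCGCGCCAAUAUC"
  target <- strsplit(revcomp_rna(mir), "")[[1]]
  # mismatch at miRNA position 3 (core, x2) and G:U at position 15 (outside)
  target[21 - 3 + 1] <- "C"   # miRNA pos 3 is "A": A:C mismatch
  stopifnot(substr(mir, 15, 15) == "C")
  # make position 15 a U:G wobble by mutating the miRNA base to U
  mir2 <- mir
  substr(mir2, 15, 15) <- "U"
  target[21 - 15 + 1] <- "G"
  sc <- score_duplex(mir2, paste(target, collapse = ""))
  expect_equal(sc$score, 2.0 + 0.5)
  expect_equal(sc$score, oracle_duplex_score(mir2, paste(target, collapse = "")))
})

test_that("duplex scores match the per-position oracle on random duplexes", {
  set.seed(19)
  bases <- c("A", "C", "G", "U")
  for (i in 1:300) {
    L <- sample(8:24, 1)
    mir <- paste(sample(bases, L, replace = TRUE), collapse = "")
    win <- paste(sample(bases, L, replace = TRUE), collapse = "")
    expect_equal(score_duplex(mir, win)$score, oracle_duplex_score(mir, win))
  }
})

test_that("adding a penalty-bearing position never decreases the score", {
  set.seed(29)
  mir <- "UGAUUGAGCCGCGCCAAUAUC"
  perfect <- strsplit(revcomp_rna(mir), "")[[1]]
  pos <- sample(21, 6)
  cur <- perfect
  prev <- 0
  for (p in pos) {
    cur[p] <- setdiff(c("A", "C", "G", "U"), cur[p])[1]
    sc <- score_duplex(mir, paste(cur, collapse = ""))$score
    expect_gte(sc, prev)
    prev <- sc
  }
})

test_that("transcript scan retains the 4.5 boundary and locates the cleavage site", {
  mir <- "UGAUUGAGCCGCGCCAAUAUC"
  site <- gsub("U", "T", revcomp_rna(mir))
  set.seed(37)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  tx <- paste0(flank(100), site, flank(80))
  hits <- scan_transcript(mir, tx)
  expect_equal(hits$start[1], 100L)
  expect_equal(hits$score[1], 0)
  expect_equal(hits$cleavage_site[1], 100L + 21L - 10L)

  # exactly 4.5: four mismatches at positions 14,16,18,21 (x1) plus one G:U
  # wobble at position 1 (x1, outside core)
  degr <- strsplit(site, "")[[1]]
  for (p in c(14, 16, 18)) {
    i <- 21 - p + 1
    degr[i] <- c(A = "C", C = "A", G = "A", T = "C")[degr[i]]
  }
  # p = 21 mismatch
  degr[1] <- c(A = "C", C = "A", G = "A", T = "C")[degr[1]]
  # p = 1 wobble: miRNA ends ...C at pos 21? position 1 base:
  p1 <- substr(mir, 1, 1)  # "U": wobble U:G -> target base G
  degr[21] <- "G"
  tx2 <- paste0(flank(50), paste(degr, collapse = ""), flank(50))
  sc <- score_duplex(mir, paste(degr, collapse = ""))$score
  expect_equal(sc, 4.5)
  hits2 <- scan_transcript(mir, tx2, score_max = 4.5)
  expect_true(50L %in% hits2$start)  # boundary inclusive
  hits3 <- scan_transcript(mir, tx2, score_max = 4.4)
  expect_false(50L %in% hits3$start)
})

test_that("random transcripts yield no retained hits in almost all draws", {
  set.seed(41)
  bases <- c("A", "C", "G", "T")
  n_hit <- 0
  for (i in 1:200) {
    mir <- paste(sample(bases, 21, replace = TRUE), collapse = "")
    tx <- paste(sample(bases, 1000, replace = TRUE), collapse = "")
    if (nrow(scan_transcript(mir, tx, score_max = 4.5)) > 0) n_hit <- n_hit + 1
  }
  expect_lte(n_hit / 200, 0.05)
})

test_that("T-plot categories implement the rule table", {
  expect_equal(grade_cleavage(0, c(7L, 0L, 0L))$category, "0")
  expect_equal(grade_cleavage(2, c(7L, 0L, 1L))$category, "4")
  expect_equal(grade_cleavage(1, c(7L, 0L, 3L))$category, "none")
  # shared maximum
  expect_equal(grade_cleavage(0, c(5L, 5L, 1L))$category, "1")
  # above the occupied median but below the max
  expect_equal(grade_cleavage(1, c(9L, 3L, 1L, 1L))$category, "2")
  # at or below the occupied median
  expect_equal(grade_cleavage(1, c(9L, 2L, 3L, 4L))$category, "3")
  expect_error(grade_cleavage(10, c(1L, 2L)), "outside")
  expect_error(grade_cleavage(0, c(-1L, 2L)), "non-negative")
})

test_that("planted degradome sites are recovered with exact coordinates and category 0", {
  cfg <- sim_config(seed = 43)
  dg <- simulate_degradome(cfg)
  tg <- predict_targets(dg$mirna, dg$transcripts, dg$profiles)
  planted <- dg$truth[has_site == TRUE]
  hit0 <- tg[score == 0]
  expect_setequal(hit0$transcript_id, planted$transcript_id)
  m <- merge(hit0, planted, by = "transcript_id")
  expect_equal(m$start, m$site_start)
  expect_equal(m$cleavage_site.x, m$cleavage_site.y)
  expect_true(all(m$category == "0"))
})
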