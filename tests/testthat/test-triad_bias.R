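toy_genes <- function(ids, chroms) {
  g <- data.table::data.table(gene_id = ids, chrom = chroms)
  cbind(g, parse_chrom_name(chroms))
}

test_that("only 1:1:1 groups become triads", {
  genes <- toy_genes(c("g1", "g2", "g3", "g4", "g5", "g1b"),
                     c("1A", "1B", "1D", "2A", "2B", "1A"))
  groups <- data.table::data.table(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    homoeolog_group = c("G1", "G1", "G1", "G2", "G2"))
  res <- detect_triads(genes, groups)
  expect_equal(nrow(res$triads), 1L)
  expect_equal(res$triads$a_id, "g1")
  expect_equal(res$non_triads$cardinality, "1:1:0")

  # 2:1:1 is not a triad
  groups2 <- rbind(groups[homoeolog_group == "G1"],
                   data.table::data.table(gene_id = "g1b", homoeolog_group = "G1"))
  res2 <- detect_triads(genes, groups2)
  expect_equal(nrow(res2$triads), 0L)
  expect_equal(res2$non_triads$cardinality, "2:1:1")

  # one gene in two groups is an error
  bad <- rbind(groups, data.table::data.table(gene_id = "g1", homoeolog_group = "G9"))
  expect_error(detect_triads(genes, bad), "more than one")
})

test_that("triad retention rate is 3 x triads / family size", {
  r <- triad_retention_rate(10, 2)
  expect_equal(r$fraction, 0.6)
  expect_equal(r$numerator, 6L)
  expect_equal(triad_retention_rate(10, 0)$fraction, 0)
})

test_that("bias classification matches the archetype geometry", {
  b <- classify_bias(10, 10, 10)
  expect_equal(b$category, "balanced")
  expect_equal(b$`dist.balanced`, 0)
  expect_false(b$filtered)

  expect_true(classify_bias(0.1, 0.2, 0.1)$filtered)
  expect_true(is.na(classify_bias(0.1, 0.2, 0.1)$category))

  expect_equal(classify_bias(18, 1, 1)$category, "A-dominant")
  expect_equal(oracle_nearest_archetype(c(0.9, 0.05, 0.05)), "A-dominant")
  expect_equal(classify_bias(1, 9.5, 9.5)$category, "A-suppressed")
  expect_equal(oracle_nearest_archetype(c(0.05, 0.475, 0.475)), "A-suppressed")

  expect_error(classify_bias(-1, 2, 3), "negative")
})

test_that("bias calls are scale invariant and A/B swap equivariant", {
  set.seed(11)
  tpm <- matrix(rexp(3 * 50, rate = 0.2), ncol = 3)
  base <- classify_bias(tpm[, 1], tpm[, 2], tpm[, 3])
  for (k in c(0.1, 3, 1000)) {
    scaled <- classify_bias(k * tpm[, 1], k * tpm[, 2], k * tpm[, 3],
                            min_total = 0)
    expect_equal(scaled$category, classify_bias(tpm[, 1], tpm[, 2], tpm[, 3],
                                                min_total = 0)$category)
  }
  swapped <- classify_bias(tpm[, 2], tpm[, 1], tpm[, 3])
  map <- c(balanced = "balanced",
           `A-dominant` = "B-dominant", `B-dominant` = "A-dominant",
           `D-dominant` = "D-dominant",
           `A-suppressed` = "B-suppressed", `B-suppressed` = "A-suppressed",
           `D-suppressed` = "D-suppressed")
  keep <- !base$filtered
  expect_equal(unname(map[base$category[keep]]), swapped$category[keep])
})

test_that("the assigned archetype is always the nearest one", {
  rel <- random_simplex(500)
  calls <- classify_bias(rel[, 1] * 10, rel[, 2] * 10, rel[, 3] * 10)
  dist_cols <- paste0("dist.", rownames(bias_archetypes()))
  d <- as.matrix(calls[, dist_cols, with = FALSE])
  assigned <- d[cbind(seq_len(nrow(d)), match(paste0("dist.", calls$category),
                                              dist_cols))]
  expect_true(all(assigned <= apply(d, 1, min) + 1e-12))
  # and agrees with the brute-force oracle
  oracle <- apply(rel, 1, oracle_nearest_archetype)
  expect_equal(calls$category, unname(oracle))
})

test_that("ternary coordinates map vertices correctly and invert", {
  expect_equal(unlist(ternary_coordinates(c(1, 0, 0))), c(x = 0, y = 0))
  expect_equal(unlist(ternary_coordinates(c(0, 0, 1))),
               c(x = 0.5, y = sqrt(3) / 2))
  rel <- random_simplex(100)
  xy <- ternary_coordinates(rel)
  back <- ternary_invert(xy$x, xy$y)
  expect_equal(unname(back), unname(rel), tolerance = 1e-12)
  expect_error(ternary_coordinates(c(0.5, 0.2, 0.2)), "simplex")
})

test_that("bias summaries exclude filtered calls and normalize per tissue", {
  calls <- data.table::data.table(
    tissue = "root",
    filtered = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    category = c("balanced", "balanced", "balanced", "D-suppressed", NA))
  s <- bias_summary(calls)
  expect_equal(s[tissue == "root" & category == "balanced", fraction], 0.75)
  expect_equal(s[tissue == "root", sum(fraction)], 1)

  allf <- data.table::data.table(tissue = "root", filtered = TRUE, category = NA)
  expect_warning(empty <- bias_summary(allf), "filtered")
  expect_equal(nrow(empty), 0L)
})

test_that("planted categories are recovered exactly at zero Dirichlet noise", {
  cfg <- sim_config(seed = 9, dirichlet_concentration = Inf)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(cfg, sim$truth$triads)
  calls <- classify_triads(sim$truth$triads, expr$em)
  merged <- merge(calls, expr$truth, by = c("group", "tissue"))
  expect_equal(merged$filtered, merged$below_filter)
  kept <- merged[filtered == FALSE]
  expect_equal(kept$category.x, kept$category.y)
  # and the planted sub-threshold cells are exactly the filtered ones
  expect_gt(sum(merged$filtered), 0)
})
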