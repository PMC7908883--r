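fam <- function(ids, chrom, ranks) {
  data.table::data.table(gene_id = ids, chrom = chrom, rank = ranks)
}

test_that("tandem clusters chain genes separated by at most max_gap intervening genes", {
  # 2 intervening genes -> linked
  c1 <- find_tandem_clusters(fam(c("a", "b"), "4A", c(100L, 103L)))
  expect_equal(nrow(c1), 2L)
  # 4 intervening genes -> not linked
  expect_equal(nrow(find_tandem_clusters(fam(c("a", "b"), "4A", c(100L, 105L)))), 0L)
  # chain of three with adjacent gaps of exactly 3
  c3 <- find_tandem_clusters(fam(c("a", "b", "c"), "4A", c(100L, 104L, 108L)))
  expect_equal(length(unique(c3$cluster_id)), 1L)
  expect_equal(c3$gene_id, c("a", "b", "c"))
  # brute-force check on the toy set: exactly the pairs with rank diff <= 4 link
  expect_true(all(diff(c3$rank) <= 4))
  expect_error(find_tandem_clusters(fam("a", "1A", NA_integer_)), "rank")
})

test_that("tandem clustering is order invariant and clusters are maximal", {
  g <- fam(sprintf("g%d", 1:6), c("1A", "1A", "1A", "1A", "2B", "2B"),
           c(10L, 14L, 30L, 33L, 5L, 6L))
  ref <- find_tandem_clusters(g)
  for (perm in list(6:1, sample(6))) {
    p <- find_tandem_clusters(g[perm])
    expect_equal(split(p$gene_id, p$chrom), split(ref$gene_id, ref$chrom))
  }
  # maximality: no unclustered family gene is within the gap of a cluster member
  clustered <- ref$gene_id
  outside <- g[!gene_id %in% clustered]
  for (i in seq_len(nrow(outside))) {
    same <- ref[chrom == outside$chrom[i]]
    if (nrow(same)) expect_true(all(abs(same$rank - outside$rank[i]) > 4))
  }
})

test_that("planted tandem clusters are recovered from the simulated genome", {
  sim <- simulate_genome(sim_config(seed = 17))
  family <- sim$genes[gene_id %in% sim$family$gene_id]
  cl <- find_tandem_clusters(family)
  truth <- sim$truth$tandem_clusters
  expect_equal(length(unique(cl$cluster_id)), nrow(truth))
  expect_setequal(cl$gene_id, c(truth$anchor, truth$extra))
})

test_that("segment assignment respects the half-open partition", {
  segs <- data.table::data.table(
    chrom = "1A", start = c(0L, 1000000L), end = c(1000000L, 2000000L),
    name = c("R1", "C"))
  g <- data.table::data.table(gene_id = c("a", "b"), chrom = "1A",
                              start = c(10000L, 1000000L))
  res <- segment_assign(g, segs)
  expect_equal(res$segment, c("R1", "C"))  # boundary start joins the right-open segment

  hole <- data.table::data.table(chrom = "1A", start = c(0L, 1500000L),
                                 end = c(1000000L, 2000000L), name = c("R1", "C"))
  expect_error(segment_assign(g, hole), "partition")
  expect_error(
    segment_assign(data.table::data.table(gene_id = "z", chrom = "1A",
                                          start = 5000000L), segs),
    "outside")
})

test_that("segment chi-square matches the hand-computed goodness of fit", {
  res <- segment_enrichment(c(C = 3L), n = 188, genome_props = c(C = 0.1067))
  # (3-20.06)^2/20.06 + (185-167.94)^2/167.94
  expect_equal(res$chi2, 16.242, tolerance = 1e-3)
  expect_lt(res$p, 0.001)
  expect_equal(res$direction, "depleted")

  # observed equal to expected gives chi2 = 0, p = 1
  flat <- segment_enrichment(c(R1 = 50L), n = 100, genome_props = c(R1 = 0.5))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  # tiny expected counts fall back to the exact binomial test
  expect_warning(
    bt <- segment_enrichment(c(C = 2L), n = 5, genome_props = c(C = 0.01)),
    "binomial")
  expect_equal(bt$test, "binomial")
})

test_that("chi-square agrees with the exact binomial oracle in direction and significance", {
  cases <- list(c(obs = 3, p = 0.1067), c(obs = 56, p = 0.18),
                c(obs = 20, p = 0.10), c(obs = 2, p = 0.05))
  for (cs in cases) {
    chi <- segment_enrichment(c(S = as.integer(cs["obs"])), n = 188,
                              genome_props = c(S = cs[["p"]]))
    bin <- binom.test(cs[["obs"]], 188, cs[["p"]])
    expect_equal(chi$direction == "depleted", cs[["obs"]] < 188 * cs[["p"]])
    expect_equal(chi$p < 0.001, bin$p.value < 0.001)
  }
})

test_that("NG86 classifies toy codon substitutions correctly", {
  same <- ng86_kaks("ATGGCT", "ATGGCT")
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)

  # TTT -> TTC is Phe -> Phe; the GGG/GGA padding contributes synonymous
  # sites so the Jukes-Cantor proportion stays in its domain
  syn <- ng86_kaks("GGGGGATTT", "GGGGGATTC")
  expect_equal(syn$ka, 0)
  expect_gt(syn$ks, 0)
  expect_equal(syn$nd, 0)
  expect_equal(syn$sd, 1)

  nsyn <- ng86_kaks("ATGGCT", "ATGGTT")  # Ala -> Val
  expect_equal(nsyn$ks, 0)
  expect_gt(nsyn$ka, 0)
  expect_equal(nsyn$nd, 1)

  expect_error(ng86_kaks("ATG", "ATGGCT"), "lengths differ")
  expect_error(ng86_kaks("ATGG", "ATGC"), "divisible by 3")
  expect_error(ng86_kaks("TAAGCT", "TAAGCT"), "stop")
})

test_that("NG86 is symmetric and total sites equal three per codon", {
  set.seed(23)
  cfg <- sim_config(seed = 23, n_cds_pairs_per_class = 3, cds_n_codons = 50,
                    cds_n_mutations = 10)
  pairs <- simulate_cds_pairs(cfg)
  for (i in seq_len(nrow(pairs))) {
    f <- ng86_kaks(pairs$cds_a[i], pairs$cds_b[i])
    r <- ng86_kaks(pairs$cds_b[i], pairs$cds_a[i])
    expect_equal(f$ka, r$ka)
    expect_equal(f$ks, r$ks)
    expect_equal(f$s_sites + f$n_sites, 3 * 50)
  }
})

test_that("planted substitution classes give the expected Ka/Ks signatures", {
  cfg <- sim_config(seed = 31, n_cds_pairs_per_class = 4, cds_n_codons = 100,
                    cds_n_mutations = 15)
  pairs <- simulate_cds_pairs(cfg)
  kk <- kaks_table(pairs)
  kk[, class := pairs$class[match(pair_id, pairs$pair_id)]]
  expect_true(all(kk[class == "synonymous", ka] == 0))
  expect_true(all(kk[class == "synonymous", ks] > 0))
  expect_true(all(kk[class == "nonsynonymous", ks] == 0))
  expect_true(all(kk[class == "nonsynonymous", ka] > 0))
})
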