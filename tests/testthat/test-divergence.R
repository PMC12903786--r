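test_that("NG86 estimates agree with the brute-force oracle", {
  # the worked 6-codon pair
  a <- "ATGGCTTTTAAAGGGTGC"
  b <- "ATGGCCTTCAAAGGATGC"
  est <- estimate_ks_ka(a, b)
  orc <- oracle_ng86(a, b)
  expect_equal(est$s_sites, orc$s_sites, tolerance = 1e-12)
  expect_equal(est$n_sites, orc$n_sites, tolerance = 1e-12)
  expect_equal(est$sd, orc$sd, tolerance = 1e-12)
  expect_equal(est$nd, orc$nd, tolerance = 1e-12)
  expect_equal(est$ks, orc$ks)
  expect_equal(est$ka, orc$ka, tolerance = 1e-12)

  # randomized pairs, including multi-hit codons and stops from
  # unconstrained mutation
  for (i in 1:25) {
    anc <- oracle_random_cds(15, seed = 100 + i)
    der <- oracle_mutate(anc, n_mut = 8, seed = 200 + i)
    est <- estimate_ks_ka(anc, der)
    orc <- oracle_ng86(anc, der)
    expect_equal(est$n_codons_used, orc$n_codons_used)
    expect_equal(est$s_sites, orc$s_sites, tolerance = 1e-9)
    expect_equal(est$sd, orc$sd, tolerance = 1e-9)
    expect_equal(est$nd, orc$nd, tolerance = 1e-9)
    expect_equal(est$ks, orc$ks, tolerance = 1e-9)
    expect_equal(est$ka, orc$ka, tolerance = 1e-9)
  }
})

test_that("NG86 basic contracts: identity, symmetry, site totals", {
  cds <- oracle_random_cds(30, seed = 1)
  est <- estimate_ks_ka(cds, cds)
  expect_identical(est$ks, 0)
  expect_identical(est$ka, 0)
  # synonymous + nonsynonymous site fractions sum to 3 per codon
  expect_equal(est$s_sites + est$n_sites, 3 * est$n_codons_used,
               tolerance = 1e-9)

  for (i in 1:10) {
    anc <- oracle_random_cds(20, seed = 300 + i)
    der <- oracle_mutate(anc, 6, seed = 400 + i)
    ab <- estimate_ks_ka(anc, der)
    ba <- estimate_ks_ka(der, anc)
    expect_equal(unclass(ab), unclass(ba), tolerance = 1e-12)
  }
})

test_that("NG86 input validation and codon dropping", {
  expect_error(estimate_ks_ka("ATGGCT", "ATG"), "equal length")
  expect_error(estimate_ks_ka("ATGG", "ATGG"), "multiple of 3")
  # N-containing and stop codons are dropped pairwise
  est <- estimate_ks_ka("ATGNNNAAA", "ATGCCCAAA")
  expect_equal(est$n_codons_used, 2)
  est2 <- estimate_ks_ka("ATGTAAAAA", "ATGCAAAAA")  # TAA stop in seq a
  expect_equal(est2$n_codons_used, 2)
  expect_error(estimate_ks_ka("NNN", "NNN"), "no usable codons")
})

test_that("NG86 recovers targets with small bias across the Ks range", {
  for (target in c(0.05, 0.5)) {
    ks_hat <- vapply(1:15, function(s) {
      sim <- simulate_codon_pair(2000, target, 0.1, seed = 1000 + s)
      estimate_ks_ka(sim$ancestral, sim$derived)$ks
    }, numeric(1))
    expect_lt(abs(mean(ks_hat) - target) / target, 0.15)
  }
  ka_hat <- vapply(1:15, function(s) {
    sim <- simulate_codon_pair(2000, 0.3, 0.3, seed = 2000 + s)
    estimate_ks_ka(sim$ancestral, sim$derived)$ka
  }, numeric(1))
  expect_lt(abs(mean(ka_hat) - 0.3) / 0.3, 0.15)
})

test_that("Kimura 2-parameter distance matches its closed form", {
  expect_equal(kimura2p_distance("ACGT", "ACGT"), 0)
  # 100 sites, 10 transitions, 0 transversions
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
  expect_equal(kimura2p_distance(a, b), 100 * (-0.5 * log(0.8)),
               tolerance = 1e-12)
  # 100 sites, 0 transitions, 10 transversions:
  # -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)) with P = 0, Q = 0.1
  b2 <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  expect_equal(kimura2p_distance(a, b2),
               100 * (-0.5 * log(0.9 * sqrt(0.8))), tolerance = 1e-12)
  # cross-check against ape on the same pair
  mat <- rbind(a = strsplit(tolower(a), "")[[1]],
               b = strsplit(tolower(b2), "")[[1]])
  expect_equal(kimura2p_distance(a, b2),
               100 * as.numeric(ape::dist.dna(ape::as.DNAbin(mat),
                                              model = "K80")),
               tolerance = 1e-9)
  # positions with N are skipped
  expect_equal(kimura2p_distance("AANA", "AANA"), 0)
  # saturation gives NA with a flag, not an error
  sat <- kimura2p_distance(paste(rep("A", 10), collapse = ""),
                           paste(rep("C", 10), collapse = ""))
  expect_true(is.na(sat))
  expect_true(attr(sat, "saturated"))
  # K2P equals JC when transitions are one third of differences
  p <- 0.12
  k2p <- 100 * (-0.5 * log(1 - 2 * (p / 3) - 2 * p / 3) -
                  0.25 * log(1 - 2 * (2 * p / 3)))
  jc <- 100 * (-0.75 * log(1 - 4 * p / 3))
  expect_equal(k2p, jc, tolerance = 1e-12)
})

test_that("tandem filter removes same-chromosome pairs under 200 bp", {
  feats <- data.frame(
    gene_id = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2",
              "chr3", "chr3"),
    start = c(0L, 1150L, 0L, 1250L, 0L, 0L, 0L, 500L),
    end = c(1000L, 2000L, 1000L, 2000L, 1000L, 1000L, 1000L, 1500L),
    strand = "+", source_label = NA)
  pairs <- data.frame(gene_a = c("a1", "b1", "c1", "d1"),
                      gene_b = c("a2", "b2", "c2", "d2"))
  out <- filter_tandem_pairs(pairs, feats)
  expect_identical(out$gene_a, pairs$gene_a)  # order preserved
  expect_true(out$tandem_removed[1])          # gap 150 < 200
  expect_false(out$tandem_removed[2])         # gap 250 >= 200
  expect_false(out$tandem_removed[3])         # different chromosomes
  expect_true(out$tandem_removed[4])          # overlap counts as gap 0

  expect_error(filter_tandem_pairs(
    data.frame(gene_a = "zz", gene_b = "a1"), feats), "zz")
})

test_that("tandem filter removes exactly the planted pairs", {
  sim <- simulate_collinear_dataset(
    data.frame(weight = 1, mean = 0.2, sd = 0.05),
    n_pairs = 120, tandem_fraction = 0.1, seed = 21, n_codons = 40)
  pairs <- sim$blocks
  out <- filter_tandem_pairs(pairs, sim$features)
  expect_identical(out$tandem_removed, sim$truth$tandem)
})

test_that("Ks distributions summarize retained pairs per block", {
  pairs <- data.frame(
    block_id = c("b1", "b1", "b2", "b3"),
    gene_a = c("x1", "x2", "x3", "x4"),
    gene_b = c("y1", "y2", "y3", "y4"),
    ks = c(0.1, 0.3, 0.5, NA),
    tandem_removed = c(FALSE, FALSE, TRUE, FALSE))
  expect_message(dist <- build_ks_distribution(pairs), "2 block")
  expect_equal(dist$pair_values, c(0.1, 0.3))
  expect_equal(dist$blocks$mean_ks, 0.2)
  expect_equal(dist$blocks$median_ks, 0.2)
  expect_equal(dist$n_dropped_blocks, 2)  # b2 tandem-only, b3 saturated
})

test_that("distribution moments track the planted mixture", {
  sim <- simulate_collinear_dataset(
    data.frame(weight = 1, mean = 0.3, sd = 0.03),
    n_pairs = 60, tandem_fraction = 0, seed = 31, n_codons = 400)
  ests <- ks_for_blocks(sim$blocks, sim$cds)
  filt <- filter_tandem_pairs(ests, sim$features)
  dist <- build_ks_distribution(filt)
  expect_equal(length(dist$pair_values), 60)
  expect_equal(mean(dist$pair_values), 0.3, tolerance = 0.03)
})
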