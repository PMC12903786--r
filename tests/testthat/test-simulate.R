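test_that("codon-pair simulation honours zero targets and determinism", {
  sim <- simulate_codon_pair(50, 0, 0, seed = 1)
  expect_identical(sim$ancestral, sim$derived)

  a <- simulate_codon_pair(100, 0.3, 0.1, seed = 42)
  b <- simulate_codon_pair(100, 0.3, 0.1, seed = 42)
  expect_identical(a, b)
  c <- simulate_codon_pair(100, 0.3, 0.1, seed = 43)
  expect_false(identical(a$derived, c$derived))
})

test_that("saturating divergence targets are refused with a diagnostic", {
  expect_error(simulate_codon_pair(100, target_ks = 5, seed = 1),
               "saturation")
})

test_that("synonymous-only simulation yields Ka = 0 exactly", {
  for (s in 1:10) {
    sim <- simulate_codon_pair(300, target_ks = 0.5, target_ka = 0,
                               seed = s)
    est <- estimate_ks_ka(sim$ancestral, sim$derived)
    expect_identical(est$ka, 0)
    expect_identical(est$nd, 0)
  }
})

test_that("estimator recovers the planted Ks at n = 2000 codons", {
  # simulation/estimation consistency: mean over 50 seeds within +-0.03
  # of the 0.2 target
  ks_hat <- vapply(1:50, function(s) {
    sim <- simulate_codon_pair(2000, target_ks = 0.2, target_ka = 0,
                               seed = s)
    estimate_ks_ka(sim$ancestral, sim$derived)$ks
  }, numeric(1))
  expect_lt(abs(mean(ks_hat) - 0.2), 0.03)
})

test_that("TE profiles carry analytic crossing truth", {
  # same distribution on both sides: no robust crossing expected
  spec_same <- list(
    sg1 = list(label = "SG1", n_copies = 3000, weights = 1, means = 15,
               sds = 4),
    sg2 = list(label = "SG2", n_copies = 3000, weights = 1, means = 15,
               sds = 4))
  sim <- simulate_te_profiles(spec_same, seed = 1)
  expect_length(sim$truth$crossings, 0)

  # equal-sd normals cross once at the midpoint by symmetry
  spec_sym <- list(
    sg1 = list(label = "SG1", n_copies = 5000, weights = 1, means = 20,
               sds = 4),
    sg2 = list(label = "SG2", n_copies = 5000, weights = 1, means = 12,
               sds = 4))
  sim2 <- simulate_te_profiles(spec_sym, seed = 2)
  expect_length(sim2$truth$crossings, 1)
  expect_equal(sim2$truth$crossings, 16, tolerance = 1e-6)

  # determinism and the low-copy warning
  sim3 <- simulate_te_profiles(spec_sym, seed = 2)
  expect_identical(sim2$profiles, sim3$profiles)
  spec_small <- spec_sym
  spec_small$sg1$n_copies <- 20
  expect_warning(simulate_te_profiles(spec_small, seed = 1), "unstable")
})

test_that("collinear dataset plants tandem geometry and Ks truth", {
  sim <- simulate_collinear_dataset(
    data.frame(weight = c(0.5, 0.5), mean = c(0.05, 0.35),
               sd = c(0.02, 0.05)),
    n_pairs = 40, tandem_fraction = 0.25, seed = 9, n_codons = 60)
  expect_equal(sum(sim$truth$tandem), 10)
  expect_equal(nrow(sim$blocks), 40)
  expect_length(sim$cds, 80)
  # planted tandem pairs share a chromosome with a < 200 bp gap
  for (i in which(sim$truth$tandem)) {
    fa <- sim$features[sim$features$gene_id == sim$truth$gene_a[i], ]
    fb <- sim$features[sim$features$gene_id == sim$truth$gene_b[i], ]
    expect_identical(fa$chrom, fb$chrom)
    gap <- max(fa$start, fb$start) - min(fa$end, fb$end)
    expect_lt(gap, 200)
  }
  # non-tandem pairs sit on different chromosomes
  i <- which(!sim$truth$tandem)[1]
  fa <- sim$features[sim$features$gene_id == sim$truth$gene_a[i], ]
  fb <- sim$features[sim$features$gene_id == sim$truth$gene_b[i], ]
  expect_false(fa$chrom == fb$chrom)

  empty <- simulate_collinear_dataset(
    data.frame(weight = 1, mean = 0.1, sd = 0.01), n_pairs = 0, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_length(empty$cds, 0)
})

test_that("count-matrix simulation is seed-deterministic and validated", {
  tree <- example_species_tree()
  a <- simulate_count_matrix(tree, 50, 3, acanthus_class_a, effect = 2,
                             seed = 7)
  b <- simulate_count_matrix(tree, 50, 3, acanthus_class_a, effect = 2,
                             seed = 7)
  expect_identical(a, b)
  expect_equal(dim(a$counts), c(50, 19))
  expect_setequal(colnames(a$counts), tree$tip.label)
  expect_length(a$truth, 3)
  expect_error(
    simulate_count_matrix(tree, 3, 5, acanthus_class_a, effect = 1),
    "planted")
})

test_that("retention chromosome truth matches direct expectations", {
  all_a <- simulate_retention_chromosome(10, "A", window = 10)
  expect_equal(all_a$truth$A, 1.0)

  alt <- simulate_retention_chromosome(100, c("A", "B"), window = 10,
                                       step = 10)
  expect_true(all(alt$truth$A == 0.5))
  expect_true(all(alt$truth$B == 0.5))
})
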