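test_that("outlier screen flags isolated carriers only", {
  # a lone carrier can only reach z = (n-1)/sqrt(n), so the z > 3 rule
  # needs a panel of a dozen or more species to bite at all
  m <- rbind(
    flat = rep(2, 12),                       # zero variance: retained
    spike = c(1000, rep(2, 11)),             # one extreme carrier
    high = c(40, 42, 38, 41, 39, 40, 41, 38, 42, 40, 39, 41))
  colnames(m) <- paste0("s", 1:12)
  out <- zscore_outlier_screen(m)
  expect_identical(out$flagged, "spike")
  expect_setequal(rownames(out$retained), c("flat", "high"))

  # agreement with an independently computed z rule on log1p counts
  for (row in rownames(m)) {
    l <- log1p(m[row, ])
    z <- if (sd(l) > 0) (l - mean(l)) / sd(l) else rep(0, length(l))
    carriers <- sum(z > 3)
    expect_identical(row %in% out$flagged,
                     carriers >= 1 && carriers <= 2)
  }
})

test_that("Blomberg's K matches phytools and behaves under BM", {
  tree <- balanced_tree(16)
  set.seed(101)
  for (i in 1:5) {
    x <- bm_trait(tree)
    expect_equal(blomberg_k(x, tree),
                 as.numeric(phytools::phylosig(tree, x, method = "K")),
                 tolerance = 1e-6)
  }
  # mean ~1 under BM; shuffled traits lose signal
  set.seed(102)
  k_bm <- replicate(500, blomberg_k(bm_trait(tree), tree))
  expect_gt(mean(k_bm), 0.9)
  expect_lt(mean(k_bm), 1.1)
  k_iid <- replicate(500, blomberg_k(
    stats::setNames(rnorm(16), tree$tip.label), tree))
  expect_lt(median(k_iid), 0.5)

  # a clade-structured trait carries more signal than BM expects
  clade <- stats::setNames(rep(c(0, 1), each = 8), tree$tip.label)
  expect_gt(blomberg_k(clade, tree), 1)

  expect_true(is.na(blomberg_k(
    stats::setNames(rep(1, 16), tree$tip.label), tree)))
  tiny <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_error(blomberg_k(c(a = 1, b = 2, c = 3), tiny), "4 tips")
})

test_that("Pagel's lambda matches phytools and separates BM from noise", {
  tree <- balanced_tree(32)
  set.seed(111)
  for (i in 1:5) {
    # BM diluted with white noise keeps the ML estimate interior, where
    # the two implementations must agree; phytools searches past 1, so
    # boundary hits are compared against the cap
    x <- bm_trait(tree) + rnorm(32, sd = 0.4)
    ours <- pagel_lambda(x, tree)
    ph <- phytools::phylosig(tree, x, method = "lambda")
    if (ph$lambda < 0.999) {
      expect_equal(ours$lambda, ph$lambda, tolerance = 1e-3)
    } else {
      expect_gt(ours$lambda, 0.99)
    }
  }
  set.seed(112)
  lam_bm <- replicate(200, pagel_lambda(bm_trait(tree), tree)$lambda)
  expect_gt(mean(lam_bm), 0.8)
  lam_iid <- replicate(200, pagel_lambda(
    stats::setNames(rnorm(32), tree$tip.label), tree)$lambda)
  expect_lt(median(lam_iid), 0.2)
})

test_that("lambda = 0 likelihood equals the star-phylogeny likelihood", {
  tree <- balanced_tree(8)
  set.seed(121)
  x <- stats::setNames(rnorm(8, sd = 2), tree$tip.label)
  C <- ape::vcv(tree)
  # at lambda 0 the covariance is diagonal: independent normals with a
  # common (profiled) mean and per-tip variance sigma2 * diag(C)
  n <- 8
  d <- diag(C)
  a <- sum(x / d) / sum(1 / d)
  s2 <- sum((x - a)^2 / d) / n
  star_ll <- sum(dnorm(x, a, sqrt(s2 * d), log = TRUE))
  direct <- pagel_lambda(x, tree, lambda_max = 1e-12)
  expect_equal(direct$loglik, star_ll, tolerance = 1e-6)
})

test_that("signal statistics are invariant to tip-order permutation", {
  tree <- balanced_tree(16)
  set.seed(131)
  x <- bm_trait(tree)
  perm <- sample(names(x))
  expect_equal(blomberg_k(x[perm], tree), blomberg_k(x, tree),
               tolerance = 1e-12)
  expect_equal(pagel_lambda(x[perm], tree)$lambda,
               pagel_lambda(x, tree)$lambda, tolerance = 1e-9)
})

test_that("signal filter applies the conjunction of thresholds", {
  tree <- example_species_tree()
  sim <- simulate_count_matrix(tree, 60, 0, acanthus_class_a,
                               effect = 0, seed = 141)
  res <- suppressMessages(signal_filter(sim$counts, tree))
  st <- res$stats
  kept <- st$orthogroup[st$defined & st$blomberg_k > 1 &
                          st$pagel_lambda > 0.5]
  expect_setequal(rownames(res$retained), kept)

  # planted high-signal rows survive at >= 80% under strong effect
  sim2 <- simulate_count_matrix(tree, 40, 10, acanthus_class_a,
                                effect = 6, seed = 142)
  res2 <- suppressMessages(signal_filter(sim2$counts, tree))
  expect_gte(mean(sim2$truth %in% rownames(res2$retained)), 0.8)
})

test_that("Welch screen matches the formula oracle and t.test", {
  xa <- c(5, 5, 6, 5)
  xb <- c(1, 1, 2, 1, 1)
  counts <- rbind(OGa = c(round(expm1(xa)), round(expm1(xb))))
  colnames(counts) <- paste0("s", 1:9)
  labels <- stats::setNames(rep(c("A", "B"), c(4, 5)), colnames(counts))
  res <- welch_screen(counts, labels, alpha = 0.1)
  la <- log1p(counts[1, 1:4]); lb <- log1p(counts[1, 5:9])
  orc <- oracle_welch(la, lb)
  expect_equal(res$tests$t, orc$t, tolerance = 1e-9)
  expect_equal(res$tests$df, orc$df, tolerance = 1e-9)
  expect_equal(res$tests$p, orc$p, tolerance = 1e-9)
  tt <- t.test(la, lb)
  expect_equal(res$tests$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(res$tests$p, tt$p.value, tolerance = 1e-9)

  # swapping the class labels negates t, p unchanged
  flipped <- stats::setNames(rep(c("B", "A"), c(4, 5)), colnames(counts))
  res2 <- welch_screen(counts, flipped, alpha = 0.1)
  expect_equal(res2$tests$t, -res$tests$t, tolerance = 1e-9)
  expect_equal(res2$tests$p, res$tests$p, tolerance = 1e-9)
})

test_that("Welch screen handles degenerate rows", {
  counts <- rbind(const = rep(3L, 6), shifted = rep(c(2L, 9L), each = 3))
  colnames(counts) <- paste0("s", 1:6)
  labels <- stats::setNames(rep(c("A", "B"), each = 3), colnames(counts))
  res <- welch_screen(counts, labels)
  expect_equal(res$tests$p[1], 1)       # identical constant classes
  expect_equal(res$tests$p[2], 0)       # constant but separated classes
  expect_setequal(rownames(res$retained), "shifted")
})

test_that("RFE keeps the contract and is deterministic", {
  tree <- example_species_tree()
  sim <- simulate_count_matrix(tree, 20, 3, acanthus_class_a,
                               effect = 6, seed = 151)
  labels <- example_class_labels()
  # candidates == n_keep: ranking only, no elimination
  r <- rfe_rank(sim$counts, labels, "regularized-linear", n_keep = 20,
                seed = 9)
  expect_equal(nrow(r), 20)
  expect_setequal(r$orthogroup, rownames(sim$counts))
  expect_equal(r$rank, 1:20)

  r2 <- rfe_rank(sim$counts, labels, "regularized-linear", n_keep = 20,
                 seed = 9)
  expect_identical(r, r2)

  expect_warning(
    rfe_rank(sim$counts, labels, "random-forest", n_keep = 30, seed = 1),
    "fewer candidates")
})

test_that("each classifier ranks strongly planted orthogroups on top", {
  tree <- example_species_tree()
  labels <- example_class_labels()
  sim <- simulate_count_matrix(tree, 200, 5, acanthus_class_a,
                               effect = 6, seed = 161)
  for (cl in c("regularized-linear", "random-forest",
               "gradient-boosted-trees")) {
    rk <- rfe_rank(sim$counts, labels, cl, n_keep = 20, seed = 7)
    expect_equal(nrow(rk), 20)
    expect_true(all(sim$truth %in% rk$orthogroup),
                label = paste("planted set in top 20 for", cl))
  }
})

test_that("full selection pipeline reports monotone stages and recalls", {
  tree <- example_species_tree()
  labels <- example_class_labels()
  sim <- simulate_count_matrix(tree, 200, 5, acanthus_class_a,
                               effect = 6, seed = 171)
  rep <- suppressMessages(
    select_lineage_orthogroups(sim$counts, tree, labels,
                               config = list(seed = 5)))
  expect_true(all(diff(rep$stage_counts) <= 0))
  expect_null(rep$terminated_at)
  expect_true(all(sim$truth %in% rep$union$orthogroup))
  # provenance column names the classifiers that picked each family
  expect_true(all(nzchar(rep$union$classifiers)))

  # deterministic given inputs and seed
  rep2 <- suppressMessages(
    select_lineage_orthogroups(sim$counts, tree, labels,
                               config = list(seed = 5)))
  expect_identical(rep$rankings, rep2$rankings)
})

test_that("pipeline terminates gracefully when a stage empties", {
  tree <- example_species_tree()
  labels <- example_class_labels()
  # all-identical rows have undefined signal: signal filter empties
  counts <- matrix(5L, nrow = 25, ncol = 19,
                   dimnames = list(sprintf("OG%02d", 1:25),
                                   tree$tip.label))
  rep <- suppressMessages(
    select_lineage_orthogroups(counts, tree, labels))
  expect_identical(rep$terminated_at, "signal_filter")
  expect_null(rep$union)
})
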