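# Synthetic-data generators. Each generator is a pure function of its
# arguments and seed (identical seeds give identical output) and returns
# the planted truth alongside the data, so every downstream stage can be
# tested for recovery without sequencing data.

.sense_codons <- function() {
  codons <- .all_codons()
  codons[.codon_aa(codons) != "*"]
}

# expected proportion of differing sites implied by a Jukes-Cantor
# distance d; the generator plants this proportion so that the
# estimator's JC correction is unbiased by construction
.jc_p <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Simulate an aligned codon pair with planted Ks and Ka
#'
#' Draws a random ancestral coding sequence and derives a partner by
#' applying Poisson numbers of synonymous-only and nonsynonymous-only
#' single-nucleotide codon edits (rejection-sampled: an edit is redrawn
#' if its class is wrong, it would create a stop codon, or its site was
#' already edited). The Poisson means are \eqn{p \times} (site count)
#' with \eqn{p = \frac{3}{4}(1 - e^{-4K/3})}, the difference proportion a
#' Jukes-Cantor process at divergence K produces, so the NG86 + JC
#' estimator recovers the targets without systematic bias.
#'
#' @param n_codons Number of codons (>= 30).
#' @param target_ks,target_ka Target divergences (>= 0); values implying
#'   a difference proportion at or beyond the JC saturation bound 0.74
#'   are refused.
#' @param seed Integer seed.
#' @return List with \code{ancestral}, \code{derived} (uppercase
#'   strings), realized edit counts \code{n_syn}, \code{n_non}, and the
#'   ancestral site counts \code{s_sites}, \code{n_sites}.
#' @export
simulate_codon_pair <- function(n_codons, target_ks = 0, target_ka = 0,
                                seed = 1) {
  stopifnot(n_codons >= 30, target_ks >= 0, target_ka >= 0)
  p_s <- .jc_p(target_ks)
  p_n <- .jc_p(target_ka)
  if (p_s >= 0.74 || p_n >= 0.74)
    stop("target divergence implies saturation (difference proportion >= ",
         "0.74); Jukes-Cantor correction cannot recover it")
  .with_seed(seed, {
    sense <- .sense_codons()
    anc <- sample(sense, n_codons, replace = TRUE)
    tabs <- .ng86_tables()
    s_sites <- sum(tabs$site[anc])
    n_sites <- 3 * n_codons - s_sites
    n_syn_target <- stats::rpois(1, p_s * s_sites)
    n_non_target <- stats::rpois(1, p_n * n_sites)
    der <- anc
    edited <- matrix(FALSE, nrow = 3, ncol = n_codons)
    gc_map <- Biostrings::GENETIC_CODE
    # An edit is accepted only if, relative to the *ancestral* codon, it
    # moves the pathway-averaged NG86 difference counts by exactly +1 in
    # the intended class: sequential within-codon edits can otherwise
    # open mixed substitution pathways that leak into the other class.
    apply_edits <- function(n_target, synonymous) {
      placed <- 0L
      attempts <- 0L
      max_attempts <- 200L * (n_target + 10L)
      while (placed < n_target && attempts < max_attempts) {
        attempts <- attempts + 1L
        ci <- sample.int(n_codons, 1)
        pos <- sample.int(3, 1)
        if (edited[pos, ci]) next
        cod <- strsplit(der[ci], "")[[1]]
        nt <- sample(setdiff(.codon_alphabet, cod[pos]), 1)
        alt <- cod
        alt[pos] <- nt
        alt_codon <- paste(alt, collapse = "")
        if (gc_map[alt_codon] == "*") next
        is_syn <- gc_map[alt_codon] == gc_map[der[ci]]
        if (is_syn != synonymous) next
        sd_cur <- tabs$sd[anc[ci], der[ci]]
        nd_cur <- tabs$nd[anc[ci], der[ci]]
        sd_new <- tabs$sd[anc[ci], alt_codon]
        nd_new <- tabs$nd[anc[ci], alt_codon]
        if (is.na(sd_new)) next
        want_sd <- sd_cur + as.numeric(synonymous)
        want_nd <- nd_cur + as.numeric(!synonymous)
        if (abs(sd_new - want_sd) > 1e-12 ||
            abs(nd_new - want_nd) > 1e-12) next
        der[ci] <<- alt_codon
        edited[pos, ci] <<- TRUE
        placed <- placed + 1L
      }
      placed
    }
    n_syn <- apply_edits(n_syn_target, synonymous = TRUE)
    n_non <- apply_edits(n_non_target, synonymous = FALSE)
    list(ancestral = paste(anc, collapse = ""),
         derived = paste(der, collapse = ""),
         n_syn = n_syn, n_non = n_non,
         s_sites = s_sites, n_sites = n_sites)
  })
}

.mixture_density_fun <- function(weights, means, sds) {
  function(x) {
    out <- numeric(length(x))
    for (j in seq_along(weights))
      out <- out + weights[j] * stats::dnorm(x, means[j], sds[j])
    out
  }
}

.draw_mixture <- function(n, weights, means, sds, lower = -Inf,
                          upper = Inf) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  x <- stats::rnorm(n, means[comp], sds[comp])
  # redraw out-of-range values (truncation)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    comp_b <- sample.int(length(weights), length(bad), replace = TRUE,
                         prob = weights)
    x[bad] <- stats::rnorm(length(bad), means[comp_b], sds[comp_b])
    bad <- which(x < lower | x > upper)
  }
  x
}

# crossings of two true mixture densities over [0, 100], found on a fine
# grid and refined by uniroot; this is the analytic truth the KDE-based
# pipeline is tested against
.true_crossings <- function(f1, f2, lower = 0, upper = 100, floor = 1e-4) {
  x <- seq(lower, upper, length.out = 20001)
  g <- f1(x) - f2(x)
  s <- sign(g)
  nz <- which(s != 0)
  out <- numeric(0)
  if (length(nz) < 2) return(out)  # coincident or one-sided curves
  # walk consecutive nonzero-sign points; a sign flip between them is a
  # crossing even when the grid hits the root exactly (zero run between)
  for (k in seq_len(length(nz) - 1)) {
    i <- nz[k]; j <- nz[k + 1]
    if (s[i] * s[j] >= 0) next
    r <- if (j == i + 1) {
      stats::uniroot(function(z) f1(z) - f2(z), c(x[i], x[j]),
                     tol = 1e-8)$root
    } else {
      (x[i] + x[j]) / 2
    }
    if (max(f1(r), f2(r)) >= floor) out <- c(out, r)
  }
  sort(out)
}

#' Simulate per-subgenome TE divergence profiles
#'
#' Draws Kimura-distance values (percent) for two subgenomes from normal
#' mixtures over [0, 100], directly in divergence space. The crossing
#' points of the two true mixture densities are computed analytically and
#' returned as truth metadata, so the KDE + intersection pipeline can be
#' checked against known values.
#'
#' @param te_spec List of two per-subgenome specs, each a list with
#'   \code{label}, \code{n_copies}, \code{weights}, \code{means},
#'   \code{sds}.
#' @param seed Integer seed.
#' @return List with \code{profiles} (list of two
#'   \code{"divergence_profile"} objects: \code{label}, \code{values})
#'   and \code{truth} (list with \code{crossings}, ascending).
#' @export
simulate_te_profiles <- function(te_spec, seed = 1) {
  stopifnot(length(te_spec) == 2)
  for (sg in te_spec) {
    stopifnot(all(c("label", "n_copies", "weights", "means", "sds")
                  %in% names(sg)))
    if (abs(sum(sg$weights) - 1) > 1e-9) stop("weights must sum to 1")
    if (any(sg$sds <= 0)) stop("sds must be > 0")
    if (sg$n_copies < 50)
      warning("n_copies < 50 for ", sg$label, ": KDE will be unstable")
  }
  .with_seed(seed, {
    profiles <- lapply(te_spec, function(sg) {
      structure(list(label = sg$label,
                     values = .draw_mixture(sg$n_copies, sg$weights,
                                            sg$means, sg$sds,
                                            lower = 0, upper = 100)),
                class = "divergence_profile")
    })
    f1 <- .mixture_density_fun(te_spec[[1]]$weights, te_spec[[1]]$means,
                               te_spec[[1]]$sds)
    f2 <- .mixture_density_fun(te_spec[[2]]$weights, te_spec[[2]]$means,
                               te_spec[[2]]$sds)
    list(profiles = profiles,
         truth = list(crossings = .true_crossings(f1, f2)))
  })
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat(sprintf("divergence profile %s: %d copies, mean %.2f%%\n",
              x$label, length(x$values), mean(x$values)))
  invisible(x)
}

#' Simulate a collinear gene-pair dataset with a planted Ks mixture
#'
#' End-to-end fixture for the Ks pipeline: draws a true Ks for each gene
#' pair from a mixture, simulates aligned CDS pairs at those divergences,
#' lays genes out on chromosomes, and places a stated fraction of pairs
#' on the same chromosome closer than 200 bp to exercise the tandem
#' filter. The truth table records each pair's drawn Ks and tandem flag.
#'
#' @param mixture_spec Data frame with columns \code{weight}, \code{mean},
#'   \code{sd} (weights summing to 1; \code{sd = 0} gives a point mass).
#' @param n_pairs Number of gene pairs.
#' @param tandem_fraction Fraction of pairs planted as tandem.
#' @param seed Integer seed.
#' @param n_codons Codons per gene (default 300).
#' @param block_size Pairs per collinear block (default 5).
#' @return List with \code{features} (gene feature data frame),
#'   \code{blocks} (collinearity data frame), \code{cds} (named character
#'   vector) and \code{truth} (data frame \code{gene_a}, \code{gene_b},
#'   \code{block_id}, \code{ks_true}, \code{tandem}).
#' @export
simulate_collinear_dataset <- function(mixture_spec, n_pairs,
                                       tandem_fraction = 0, seed = 1,
                                       n_codons = 300, block_size = 5) {
  stopifnot(is.data.frame(mixture_spec),
            abs(sum(mixture_spec$weight) - 1) < 1e-9,
            n_pairs >= 0, tandem_fraction >= 0, tandem_fraction <= 1)
  empty <- list(
    features = data.frame(gene_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0),
                          source_label = character(0)),
    blocks = data.frame(block_id = character(0), gene_a = character(0),
                        gene_b = character(0)),
    cds = stats::setNames(character(0), character(0)),
    truth = data.frame(gene_a = character(0), gene_b = character(0),
                       block_id = character(0), ks_true = numeric(0),
                       tandem = logical(0)))
  if (n_pairs == 0) return(empty)
  .with_seed(seed, {
    comp <- sample.int(nrow(mixture_spec), n_pairs, replace = TRUE,
                       prob = mixture_spec$weight)
    ks_true <- stats::rnorm(n_pairs, mixture_spec$mean[comp],
                            mixture_spec$sd[comp])
    ks_true <- pmax(ks_true, 0)
    n_tandem <- round(tandem_fraction * n_pairs)
    tandem <- rep(FALSE, n_pairs)
    if (n_tandem > 0) tandem[sample.int(n_pairs, n_tandem)] <- TRUE
    gene_len <- 3L * n_codons
    rows_f <- vector("list", n_pairs)
    cds <- character(2L * n_pairs)
    cds_names <- character(2L * n_pairs)
    for (i in seq_len(n_pairs)) {
      pair_seed <- sample.int(.Machine$integer.max, 1)
      sim <- simulate_codon_pair(n_codons, target_ks = ks_true[i],
                                 target_ka = 0, seed = pair_seed)
      ga <- sprintf("g%04da", i)
      gb <- sprintf("g%04db", i)
      cds[2 * i - 1] <- sim$ancestral
      cds[2 * i] <- sim$derived
      cds_names[2 * i - 1] <- ga
      cds_names[2 * i] <- gb
      if (tandem[i]) {
        # same chromosome, gap 50 bp < 200 bp
        chrom <- sprintf("chr%04d", i)
        start_a <- 1000L
        start_b <- start_a + gene_len + 50L
        rows_f[[i]] <- data.frame(
          gene_id = c(ga, gb), chrom = chrom,
          start = c(start_a, start_b),
          end = c(start_a, start_b) + gene_len,
          strand = "+", source_label = NA_character_)
      } else {
        rows_f[[i]] <- data.frame(
          gene_id = c(ga, gb),
          chrom = c(sprintf("chr%04dA", i), sprintf("chr%04dB", i)),
          start = 1000L, end = 1000L + gene_len,
          strand = "+", source_label = NA_character_)
      }
    }
    features <- do.call(rbind, rows_f)
    block_id <- sprintf("b%03d", ceiling(seq_len(n_pairs) / block_size))
    blocks <- data.frame(block_id = block_id,
                         gene_a = cds_names[seq(1, 2 * n_pairs, by = 2)],
                         gene_b = cds_names[seq(2, 2 * n_pairs, by = 2)])
    truth <- data.frame(gene_a = blocks$gene_a, gene_b = blocks$gene_b,
                        block_id = block_id, ks_true = ks_true,
                        tandem = tandem)
    list(features = features, blocks = blocks,
         cds = stats::setNames(cds, cds_names), truth = truth)
  })
}

#' Simulate an orthogroup count matrix on a species tree
#'
#' Background counts are generated as Poisson(exp(latent)), where the
#' latent value evolves as Brownian motion on the tree plus independent
#' per-tip noise -- so the matrix carries genuine phylogenetic signal for
#' the K/lambda filters to measure. Planted orthogroups additionally
#' receive a latent-scale mean shift of \code{effect} on every class-A
#' tip (a fold change of exp(effect) in expected copy number, the way a
#' lineage-specific family expansion acts), making them
#' lineage-discriminating by construction.
#'
#' @param tree \code{ape::phylo} with branch lengths.
#' @param n_orthogroups Total number of orthogroups.
#' @param n_planted Number of planted lineage-shifted orthogroups.
#' @param class_a Character vector of class-A tip labels.
#' @param effect Latent (log Poisson-mean) shift added on class-A tips
#'   of planted rows (>= 0; 0 gives a null simulation). Strong effects
#'   are several times the per-tip noise SD.
#' @param noise SD of independent per-tip latent noise (default 0.2).
#' @param bm_sd Root-to-tip Brownian SD of the latent value (the tree
#'   covariance is normalised to unit depth, so this sets the total
#'   phylogenetic spread regardless of the tree's time scale; default
#'   1.0).
#' @param base_mean Baseline Poisson mean (default 20); large enough
#'   that Poisson sampling noise does not drown the Brownian signal the
#'   phylogenetic filters are meant to measure.
#' @param seed Integer seed.
#' @return List with \code{counts} (integer matrix with orthogroup row
#'   names, species columns) and \code{truth} (character vector of
#'   planted orthogroup ids).
#' @export
simulate_count_matrix <- function(tree, n_orthogroups, n_planted,
                                  class_a, effect, noise = 0.2,
                                  bm_sd = 1.0, base_mean = 20, seed = 1) {
  stopifnot(inherits(tree, "phylo"), n_orthogroups >= 1, effect >= 0)
  if (n_planted > n_orthogroups)
    stop("more planted orthogroups than total orthogroups")
  if (!all(class_a %in% tree$tip.label))
    stop("class_a tips absent from tree")
  .with_seed(seed, {
    tips <- tree$tip.label
    n_sp <- length(tips)
    C <- ape::vcv(tree)[tips, tips]
    C <- C / max(diag(C))  # unit depth: bm_sd is the root-to-tip SD
    U <- chol(C)
    is_a <- tips %in% class_a
    counts <- matrix(0L, nrow = n_orthogroups, ncol = n_sp,
                     dimnames = list(sprintf("OG%05d", seq_len(n_orthogroups)),
                                     tips))
    planted <- rownames(counts)[seq_len(n_planted)]
    for (i in seq_len(n_orthogroups)) {
      bm <- bm_sd * drop(t(U) %*% stats::rnorm(n_sp))
      latent <- log(base_mean) + bm + stats::rnorm(n_sp, sd = noise)
      if (i <= n_planted) latent[is_a] <- latent[is_a] + effect
      counts[i, ] <- stats::rpois(n_sp, exp(latent))
    }
    list(counts = counts, truth = planted)
  })
}

#' Simulate a chromosome with a known retention pattern
#'
#' Lays \code{n_genes} genes at regular spacing along one chromosome and
#' assigns each a progenitor source label by recycling
#' \code{source_pattern}; the truth ratios per window are computed by
#' direct counting, independently of \code{\link{retention_track}}.
#'
#' @param n_genes Number of genes.
#' @param source_pattern Character vector of source labels recycled along
#'   the chromosome; \code{NA} or \code{"unassigned"} marks genes without
#'   a collinearity assignment.
#' @param seed Integer seed (used only when \code{shuffle = TRUE}).
#' @param shuffle Randomly permute the recycled pattern.
#' @param window,step Window/step (in genes) used for the truth ratios.
#' @return List with \code{features} (gene feature data frame including
#'   \code{source_label}) and \code{truth} (data frame with one row per
#'   window: \code{window_start}, \code{window_size} and one ratio column
#'   per label).
#' @export
simulate_retention_chromosome <- function(n_genes, source_pattern,
                                          seed = 1, shuffle = FALSE,
                                          window = 100, step = 50) {
  stopifnot(n_genes >= 1, length(source_pattern) >= 1)
  src <- rep(source_pattern, length.out = n_genes)
  if (shuffle) src <- .with_seed(seed, sample(src))
  src[is.na(src)] <- "unassigned"
  starts <- 1000L * (seq_len(n_genes) - 1L)
  features <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                         chrom = "chr1", start = starts,
                         end = starts + 500L, strand = "+",
                         source_label = ifelse(src == "unassigned",
                                               NA_character_, src))
  labels <- sort(setdiff(unique(src), "unassigned"))
  w_starts <- integer(0)
  w_sizes <- integer(0)
  ratio_rows <- list()
  s <- 1L
  repeat {
    e <- min(s + window - 1L, n_genes)
    size <- e - s + 1L
    in_win <- src[s:e]
    ratio_rows[[length(ratio_rows) + 1L]] <-
      vapply(labels, function(l) sum(in_win == l) / size, numeric(1))
    w_starts <- c(w_starts, s - 1L)
    w_sizes <- c(w_sizes, size)
    if (e == n_genes) break
    s <- s + step
    if (s > n_genes) break
  }
  truth <- cbind(data.frame(window_start = w_starts, window_size = w_sizes),
                 as.data.frame(do.call(rbind, ratio_rows)))
  list(features = features, truth = truth)
}

#' A fixed 19-taxon species tree for demonstrations and simulations
#'
#' An ultrametric tree mirroring a typical comparative set for mangrove
#' Acanthaceae: a four-tip focal clade (two diploid progenitor species
#' plus the two subgenomes of their allotetraploid, tips \code{Ail},
#' \code{Aeb}, \code{SG1}, \code{SG2}) embedded among 15 background taxa.
#' The focal clade has the long-stem/recent-crown shape typical of such
#' lineages (a deep divergence from its terrestrial relatives, recent
#' speciation and hybridization), which is what makes clade-wide
#' copy-number shifts phylogenetically coherent. Branch lengths are in
#' arbitrary time units.
#'
#' @return An \code{ape::phylo} with 19 tips.
#' @export
example_species_tree <- function() {
  nwk <- paste0(
    "(Nfr:12,(((Lra:3,Cmi:3):6,((Sal:2,Sca:2):3,((Bpa:1.5,Rap:1.5):1.5,",
    "(Kob:1.5,Cta:1.5):1.5):2):4):2,(Aco:10,(Oeu:8,(Rgl:7,(Shi:6.5,",
    "((Scu:4,Apa:4):0.4,((Ail:0.1,SG1:0.1):0.5,(Aeb:0.1,SG2:0.1):0.5)",
    ":3.8):2.1):0.5):1):2):1):1);")
  ape::read.tree(text = nwk)
}

#' Default class labels for \code{\link{example_species_tree}}
#'
#' Class A is the focal lineage (the two progenitors and the two
#' allotetraploid subgenomes, treated as separate taxa); class B is
#' everything else.
#'
#' @return Named character vector over the 19 tips with values
#'   \code{"A"} / \code{"B"}.
#' @export
example_class_labels <- function() {
  tree <- example_species_tree()
  a <- c("Ail", "Aeb", "SG1", "SG2")
  stats::setNames(ifelse(tree$tip.label %in% a, "A", "B"),
                  tree$tip.label)
}
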