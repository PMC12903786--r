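# Independent oracles, deliberately written as plain brute-force code
# with no shared machinery with the package internals.

# Standard genetic code as a plain lookup (TCAG order, standard table).
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  i <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1
    codons[i] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracle_aa <- function(codon) unname(oracle_codon_table[[codon]])

# NG86 synonymous site fraction of one codon: fraction of the 9 possible
# single-nucleotide changes that preserve the amino acid; changes to
# stops count as nonsynonymous.
oracle_syn_sites <- function(codon) {
  bases <- c("T", "C", "A", "G")
  aa0 <- oracle_aa(codon)
  syn <- 0
  for (pos in 1:3) {
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_aa(mut) == aa0) syn <- syn + 1
    }
  }
  syn / 3
}

# All orderings of the differing positions between two codons,
# enumerated recursively; pathways through stop codons are discarded.
oracle_pathways <- function(c1, c2) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffs) == 0) return(list(list(s = 0, n = 0)))
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  paths <- list()
  for (ord in perm(diffs)) {
    cur <- c1
    s <- 0; n <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (oracle_aa(nxt) == "*") { ok <- FALSE; break }
      if (oracle_aa(nxt) == oracle_aa(cur)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) paths[[length(paths) + 1]] <- list(s = s, n = n)
  }
  paths
}

# Full brute-force NG86 + Jukes-Cantor on a pair of aligned CDS.
oracle_ng86 <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) == nchar(seq_b), nchar(seq_a) %% 3 == 0)
  nc <- nchar(seq_a) / 3
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_len(nc)) {
    ca <- substr(seq_a, 3 * i - 2, 3 * i)
    cb <- substr(seq_b, 3 * i - 2, 3 * i)
    if (grepl("[^TCAG]", ca) || grepl("[^TCAG]", cb)) next
    if (oracle_aa(ca) == "*" || oracle_aa(cb) == "*") next
    paths <- oracle_pathways(ca, cb)
    if (length(paths) == 0) next
    used <- used + 1
    S <- S + (oracle_syn_sites(ca) + oracle_syn_sites(cb)) / 2
    Sd <- Sd + mean(vapply(paths, function(p) p$s, numeric(1)))
    Nd <- Nd + mean(vapply(paths, function(p) p$n, numeric(1)))
  }
  N <- 3 * used - S
  jc <- function(p) if (p >= 0.74) NA_real_ else max(-0.75 * log(1 - 4 * p / 3), 0)
  ps <- Sd / S
  pn <- Nd / N
  list(ks = jc(ps), ka = jc(pn), s_sites = S, n_sites = N,
       sd = Sd, nd = Nd, n_codons_used = used)
}

# Welch's t-test from the textbook formulas.
oracle_welch <- function(xa, xb) {
  va <- var(xa); vb <- var(xb)
  na <- length(xa); nb <- length(xb)
  se2 <- va / na + vb / nb
  t <- (mean(xa) - mean(xb)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Random sense-codon CDS for fixture construction.
oracle_random_cds <- function(n_codons, seed) {
  set.seed(seed)
  sense <- names(oracle_codon_table)[oracle_codon_table != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Mutate a CDS at random positions (any change, may be nonsense) --
# used to produce arbitrary codon pairs for oracle comparison.
oracle_mutate <- function(seq, n_mut, seed) {
  set.seed(seed)
  bases <- c("T", "C", "A", "G")
  s <- strsplit(seq, "")[[1]]
  for (i in sample(seq_along(s), n_mut)) {
    s[i] <- sample(setdiff(bases, s[i]), 1)
  }
  paste(s, collapse = "")
}
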