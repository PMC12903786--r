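# NG86 codon counting machinery.
#
# Site fractions and pathway-averaged difference counts are precomputed once
# per session for all 64x64 codon pairs, so per-pair estimation reduces to
# table lookups and scales to genome-sized inputs.

.ng86_cache <- new.env(parent = emptyenv())

.codon_alphabet <- c("T", "C", "A", "G")

.all_codons <- function() {
  g <- expand.grid(p3 = .codon_alphabet, p2 = .codon_alphabet,
                   p1 = .codon_alphabet, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

.codon_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

# Per-codon synonymous site fraction. Mutations creating a stop codon are
# counted as nonsynonymous so that syn + nonsyn site fractions sum to 3
# exactly for every sense codon.
.ng86_site_table <- function() {
  codons <- .all_codons()
  aa <- .codon_aa(codons)
  s <- numeric(length(codons))
  names(s) <- codons
  for (i in seq_along(codons)) {
    if (aa[i] == "*") {
      s[i] <- NA_real_
      next
    }
    cod <- strsplit(codons[i], "")[[1]]
    syn <- 0
    for (pos in 1:3) {
      for (nt in setdiff(.codon_alphabet, cod[pos])) {
        alt <- cod
        alt[pos] <- nt
        alt_aa <- .codon_aa(paste(alt, collapse = ""))
        if (!is.na(alt_aa) && alt_aa == aa[i]) syn <- syn + 1
      }
    }
    s[i] <- syn / 3
  }
  s
}

# Average synonymous/nonsynonymous difference counts over all minimal
# substitution pathways between two codons, excluding pathways that pass
# through a stop codon. Returns NA counts when every pathway is blocked.
.ng86_pathway_counts <- function(c1, c2) {
  a1 <- strsplit(c1, "")[[1]]
  a2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(a1 != a2)
  d <- length(diff_pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(d),
    "1" = list(diff_pos),
    "2" = list(diff_pos, rev(diff_pos)),
    "3" = {
      p <- diff_pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  total_s <- 0
  total_n <- 0
  n_valid <- 0L
  for (ord in perms) {
    cur <- a1
    path_s <- 0
    path_n <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- a2[pos]
      aa_cur <- .codon_aa(paste(cur, collapse = ""))
      aa_nxt <- .codon_aa(paste(nxt, collapse = ""))
      if (aa_nxt == "*") { ok <- FALSE; break }
      if (aa_cur == aa_nxt) path_s <- path_s + 1 else path_n <- path_n + 1
      cur <- nxt
    }
    if (ok) {
      total_s <- total_s + path_s
      total_n <- total_n + path_n
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = total_s / n_valid, nd = total_n / n_valid)
}

.ng86_tables <- function() {
  if (!is.null(.ng86_cache$tables)) return(.ng86_cache$tables)
  codons <- .all_codons()
  n <- length(codons)
  site <- .ng86_site_table()
  aa <- .codon_aa(codons)
  sense <- which(aa != "*")
  sd_tab <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd_tab <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  for (i in sense) {
    for (j in sense) {
      if (j < i) next
      cnt <- .ng86_pathway_counts(codons[i], codons[j])
      sd_tab[i, j] <- sd_tab[j, i] <- cnt[["sd"]]
      nd_tab[i, j] <- nd_tab[j, i] <- cnt[["nd"]]
    }
  }
  .ng86_cache$tables <- list(codons = codons, site = site,
                             sd = sd_tab, nd = nd_tab)
  .ng86_cache$tables
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.74) return(NA_real_)
  max(-0.75 * log(1 - 4 * p / 3), 0)
}

.split_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq), by = 3), seq(3, nchar(seq), by = 3))
}

#' Estimate synonymous and nonsynonymous divergence (NG86)
#'
#' Computes Ks and Ka for a pair of aligned coding sequences by
#' Nei-Gojobori (1986) counting: per-codon synonymous/nonsynonymous site
#' fractions are averaged over the two sequences, differences in multi-hit
#' codons are averaged over all minimal substitution pathways that avoid
#' stop codons, and the resulting proportions are corrected for multiple
#' hits with the Jukes-Cantor formula d = -(3/4) log(1 - 4p/3).
#'
#' Codons containing \code{N} or a stop codon in either sequence are
#' dropped pairwise before counting, as are the rare codon pairs whose
#' every minimal pathway passes through a stop. A proportion of
#' differences at or beyond 0.74 is flagged as saturated and the
#' corresponding distance is \code{NA}: such pairs belong in the tail of a
#' Ks distribution but carry no usable distance.
#'
#' @param cds_a,cds_b Aligned coding sequences of equal length (a multiple
#'   of 3), as single uppercase strings over \code{A,C,G,T,N}.
#' @return An object of class \code{"substitution_estimate"}: a list with
#'   elements \code{ks}, \code{ka}, \code{s_sites}, \code{n_sites},
#'   \code{sd}, \code{nd}, \code{n_codons_used}, \code{saturated}
#'   (synonymous class) and \code{saturated_ka}.
#' @examples
#' est <- estimate_ks_ka("ATGGCTTTTAAAGGGTGC", "ATGGCCTTCAAAGGATGC")
#' est$ks
#' @export
estimate_ks_ka <- function(cds_a, cds_b) {
  cds_a <- .as_sequence(cds_a)
  cds_b <- .as_sequence(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("sequences must have equal length")
  if (nchar(cds_a) %% 3 != 0)
    stop("sequence length must be a multiple of 3")
  tabs <- .ng86_tables()
  ca <- .split_codons(cds_a)
  cb <- .split_codons(cds_b)
  aa_a <- Biostrings::GENETIC_CODE[ca]
  aa_b <- Biostrings::GENETIC_CODE[cb]
  # drop codons with N (not in the table) or stops in either sequence
  usable <- !is.na(aa_a) & !is.na(aa_b) & aa_a != "*" & aa_b != "*"
  ca <- ca[usable]
  cb <- cb[usable]
  if (length(ca) == 0L) stop("no usable codons after filtering")
  idx <- cbind(match(ca, tabs$codons), match(cb, tabs$codons))
  sd_i <- tabs$sd[idx]
  nd_i <- tabs$nd[idx]
  # codon pairs whose pathways are all stop-blocked are dropped entirely
  ok <- !is.na(sd_i)
  ca <- ca[ok]; cb <- cb[ok]; sd_i <- sd_i[ok]; nd_i <- nd_i[ok]
  if (length(ca) == 0L) stop("no usable codons after filtering")
  s_sites <- (sum(tabs$site[ca]) + sum(tabs$site[cb])) / 2
  n_sites <- 3 * length(ca) - s_sites
  sd_tot <- sum(sd_i)
  nd_tot <- sum(nd_i)
  ps <- if (s_sites > 0) sd_tot / s_sites else NA_real_
  pn <- if (n_sites > 0) nd_tot / n_sites else NA_real_
  ks <- .jc_correct(ps)
  ka <- .jc_correct(pn)
  structure(list(
    ks = ks, ka = ka,
    s_sites = s_sites, n_sites = n_sites,
    sd = sd_tot, nd = nd_tot,
    n_codons_used = length(ca),
    saturated = is.finite(ps) && ps >= 0.74,
    saturated_ka = is.finite(pn) && pn >= 0.74
  ), class = "substitution_estimate")
}

#' @export
print.substitution_estimate <- function(x, ...) {
  cat("NG86 substitution estimate\n")
  cat(sprintf("  Ks = %s  (Sd = %.2f over S = %.2f sites)\n",
              if (is.na(x$ks)) "saturated" else sprintf("%.4f", x$ks),
              x$sd, x$s_sites))
  cat(sprintf("  Ka = %s  (Nd = %.2f over N = %.2f sites)\n",
              if (is.na(x$ka)) "saturated" else sprintf("%.4f", x$ka),
              x$nd, x$n_sites))
  cat(sprintf("  codons used: %d\n", x$n_codons_used))
  invisible(x)
}

.as_sequence <- function(x) {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet"))
    x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single sequence string")
  toupper(x)
}

#' Kimura 2-parameter distance (percent)
#'
#' Nucleotide distance correcting separately for transitions and
#' transversions; the scale on which RepeatMasker reports
#' transposable-element divergence. With P and Q the transition and
#' transversion proportions over comparable sites, the distance is
#' \deqn{100 \times \left[-\tfrac12 \log\{(1 - 2P - Q)\sqrt{1 - 2Q}\}\right].}
#'
#' Positions where either sequence has a base outside \code{A,C,G,T}
#' (e.g. \code{N}) are skipped. When the logarithm's argument is
#' non-positive the distance is saturated and \code{NA} is returned with
#' attribute \code{saturated = TRUE}.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings.
#' @return Numeric percent distance in [0, 100+), or \code{NA} if
#'   saturated.
#' @export
kimura2p_distance <- function(seq_a, seq_b) {
  seq_a <- .as_sequence(seq_a)
  seq_b <- .as_sequence(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must have equal length")
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  valid <- a %in% .codon_alphabet & b %in% .codon_alphabet
  a <- a[valid]
  b <- b[valid]
  n <- length(a)
  if (n == 0L) stop("no comparable sites")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    return(structure(NA_real_, saturated = TRUE))
  100 * (-0.5 * log(arg1) - 0.25 * log(arg2))
}
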