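# Pair-level bookkeeping: the tandem-proximity filter and assembly of
# Ks distributions from collinear blocks.

#' Flag tandem-proximal gene pairs
#'
#' Recent tandem duplications generate spurious low-Ks pairs. A pair is
#' flagged (and later excluded from all Ks distributions) when both genes
#' lie on the same chromosome and the gap between their intervals is
#' smaller than \code{max_gap_bp} (default 200 bp, the WGDI convention).
#' Overlapping genes count as gap 0. Pairs on different chromosomes are
#' always kept, whatever the distance.
#'
#' @param pairs Data frame with columns \code{gene_a}, \code{gene_b} (and
#'   optionally \code{block_id}, \code{ks}).
#' @param features Gene feature table as returned by
#'   \code{\link{read_gene_features}}: columns \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end} with 0-based half-open
#'   coordinates.
#' @param max_gap_bp Gap threshold in bp; pairs with gap strictly below it
#'   are flagged.
#' @return The input data frame, in its original order, with a logical
#'   column \code{tandem_removed} added (or overwritten).
#' @export
filter_tandem_pairs <- function(pairs, features, max_gap_bp = 200) {
  stopifnot(is.data.frame(pairs), is.data.frame(features))
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), features$gene_id)
  if (length(missing) > 0)
    stop("gene(s) absent from feature table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ia <- match(pairs$gene_a, features$gene_id)
  ib <- match(pairs$gene_b, features$gene_id)
  same_chrom <- features$chrom[ia] == features$chrom[ib]
  # gap between [start,end) intervals; 0 when overlapping
  gap <- pmax(features$start[ia], features$start[ib]) -
    pmin(features$end[ia], features$end[ib])
  gap <- pmax(gap, 0)
  pairs$tandem_removed <- same_chrom & gap < max_gap_bp
  pairs
}

#' Assemble a Ks distribution from collinear blocks
#'
#' Collects the finite Ks values of retained (non-tandem, non-saturated)
#' pairs and computes per-block mean and median Ks. Blocks left empty
#' after filtering are dropped with a message; both pair-level values and
#' block-level summaries are returned because published peak positions may
#' rest on either.
#'
#' @param pairs Data frame with columns \code{block_id}, \code{gene_a},
#'   \code{gene_b}, \code{ks} and logical \code{tandem_removed} (see
#'   \code{\link{filter_tandem_pairs}}); \code{ks} may contain \code{NA}
#'   for saturated pairs.
#' @return Object of class \code{"ks_distribution"}: list with
#'   \code{pair_values} (finite Ks of retained pairs), \code{blocks}
#'   (data frame \code{block_id}, \code{n_pairs}, \code{mean_ks},
#'   \code{median_ks}) and \code{n_dropped_blocks}.
#' @export
build_ks_distribution <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("block_id", "ks") %in% names(pairs)))
  if (!"tandem_removed" %in% names(pairs)) pairs$tandem_removed <- FALSE
  keep <- !pairs$tandem_removed & is.finite(pairs$ks)
  retained <- pairs[keep, , drop = FALSE]
  all_blocks <- unique(pairs$block_id)
  kept_blocks <- unique(retained$block_id)
  n_dropped <- length(setdiff(all_blocks, kept_blocks))
  if (n_dropped > 0)
    message(n_dropped, " block(s) dropped: no retained pairs")
  if (nrow(retained) == 0) {
    blocks <- data.frame(block_id = character(0), n_pairs = integer(0),
                         mean_ks = numeric(0), median_ks = numeric(0))
  } else {
    sp <- split(retained$ks, factor(retained$block_id, levels = kept_blocks))
    blocks <- data.frame(
      block_id = kept_blocks,
      n_pairs = vapply(sp, length, integer(1)),
      mean_ks = vapply(sp, mean, numeric(1)),
      median_ks = vapply(sp, stats::median, numeric(1)),
      row.names = NULL
    )
  }
  structure(list(pair_values = retained$ks, blocks = blocks,
                 n_dropped_blocks = n_dropped),
            class = "ks_distribution")
}

#' @export
print.ks_distribution <- function(x, ...) {
  cat(sprintf("Ks distribution: %d retained pairs in %d blocks (%d blocks dropped)\n",
              length(x$pair_values), nrow(x$blocks), x$n_dropped_blocks))
  if (length(x$pair_values)) {
    q <- stats::quantile(x$pair_values, c(0.25, 0.5, 0.75))
    cat(sprintf("  pair Ks quartiles: %.3f / %.3f / %.3f\n", q[1], q[2], q[3]))
  }
  invisible(x)
}

#' Compute per-pair Ks/Ka over a collinearity table
#'
#' Convenience driver: runs \code{\link{estimate_ks_ka}} for every gene
#' pair of a collinearity table against a named set of coding sequences.
#'
#' @param blocks Collinearity data frame (\code{block_id}, \code{gene_a},
#'   \code{gene_b}).
#' @param cds Named character vector of aligned coding sequences (names
#'   are gene ids); each pair must have equal-length entries.
#' @return Data frame \code{gene_a}, \code{gene_b}, \code{block_id},
#'   \code{ks}, \code{ka}, \code{saturated}.
#' @export
ks_for_blocks <- function(blocks, cds) {
  stopifnot(is.data.frame(blocks), is.character(cds))
  missing <- setdiff(unique(c(blocks$gene_a, blocks$gene_b)), names(cds))
  if (length(missing) > 0)
    stop("sequence(s) missing for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  res <- lapply(seq_len(nrow(blocks)), function(i) {
    est <- estimate_ks_ka(cds[[blocks$gene_a[i]]], cds[[blocks$gene_b[i]]])
    data.frame(gene_a = blocks$gene_a[i], gene_b = blocks$gene_b[i],
               block_id = blocks$block_id[i],
               ks = est$ks, ka = est$ka, saturated = est$saturated)
  })
  do.call(rbind, res)
}
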