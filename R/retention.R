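# Windowed progenitor gene-retention tracks along allopolyploid
# chromosomes.

#' Windowed gene-retention ratios along a chromosome
#'
#' Slides a window of \code{window} consecutive genes (ordered by start
#' coordinate) in steps of \code{step} genes and, for each window and
#' each progenitor source label, reports the fraction of genes carrying
#' that label. Genes without a collinearity assignment count toward the
#' denominator as \code{"unassigned"}, so regions lacking homologous
#' matches show up as windows whose labelled ratios sum below 1. The
#' final partial window is included with its own (smaller) denominator.
#'
#' Windows are measured in gene index rather than bp so that
#' repeat-dense regions do not distort the track.
#'
#' @param features Gene feature data frame for one chromosome: columns
#'   \code{gene_id}, \code{chrom}, \code{start} and \code{source_label}
#'   (NA or \code{""} means unassigned).
#' @param window Window size in genes (default 100).
#' @param step Step between window starts in genes (default 50).
#' @return Object of class \code{"retention_track"}: list with
#'   \code{chrom}, \code{window_starts} (0-based gene-index offsets),
#'   \code{window_sizes} and \code{ratios}, a matrix with one row per
#'   window and one column per source label (unassigned excluded from the
#'   columns; each row's labelled ratios sum to <= 1).
#' @export
retention_track <- function(features, window = 100, step = 50) {
  stopifnot(is.data.frame(features), window >= 1, step >= 1)
  if (nrow(features) == 0) {
    warning("empty chromosome: empty track")
    return(structure(list(chrom = NA_character_,
                          window_starts = integer(0),
                          window_sizes = integer(0),
                          ratios = matrix(numeric(0), nrow = 0, ncol = 0)),
                     class = "retention_track"))
  }
  if (length(unique(features$chrom)) > 1)
    stop("features span multiple chromosomes; call per chromosome")
  features <- features[order(features$start), , drop = FALSE]
  src <- features$source_label
  if (is.null(src)) src <- rep(NA_character_, nrow(features))
  src[is.na(src) | src == ""] <- "unassigned"
  labels <- sort(setdiff(unique(src), "unassigned"))
  n <- nrow(features)
  starts <- seq(1L, n, by = step)
  # drop redundant trailing starts fully covered by the previous window
  starts <- starts[starts == 1L | starts + 0L <= n]
  window_starts <- integer(0)
  window_sizes <- integer(0)
  rows <- list()
  for (s in starts) {
    e <- min(s + window - 1L, n)
    size <- e - s + 1L
    counts <- table(factor(src[s:e], levels = c(labels, "unassigned")))
    rows[[length(rows) + 1L]] <- as.numeric(counts[labels]) / size
    window_starts <- c(window_starts, s - 1L)
    window_sizes <- c(window_sizes, size)
    if (e == n) break
  }
  ratios <- do.call(rbind, rows)
  if (is.null(ratios)) ratios <- matrix(numeric(0), nrow = 0,
                                        ncol = length(labels))
  colnames(ratios) <- labels
  structure(list(chrom = features$chrom[1], window_starts = window_starts,
                 window_sizes = window_sizes, ratios = ratios),
            class = "retention_track")
}

#' @export
print.retention_track <- function(x, ...) {
  cat(sprintf("retention track on %s: %d windows, sources: %s\n",
              x$chrom, length(x$window_starts),
              paste(colnames(x$ratios), collapse = ", ")))
  invisible(x)
}

#' @export
plot.retention_track <- function(x, ...) {
  if (nrow(x$ratios) == 0) stop("empty track")
  mids <- x$window_starts + x$window_sizes / 2
  graphics::matplot(mids, x$ratios, type = "l", lty = 1, ylim = c(0, 1),
                    xlab = "gene index", ylab = "retention ratio",
                    main = x$chrom, ...)
  graphics::legend("topright", legend = colnames(x$ratios),
                   lty = 1, col = seq_len(ncol(x$ratios)), bty = "n")
  invisible(x)
}
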