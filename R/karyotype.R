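# Karyotype event arithmetic: how a haploid chromosome number evolves
# under whole-genome duplication, fission, fusion and hybridization.

#' Apply a chain of karyotype events
#'
#' Starting from a haploid chromosome count, applies in order: \code{"WGD"}
#' (n -> 2n), \code{"fission"} (n -> n + 1), \code{"fusion"} (n -> n - 1)
#' or hybridization with a second genome, written either as the string
#' \code{"hybridize:<m>"} or as a list element
#' \code{list(type = "hybridize", other_n = m)} (n -> n + m). The full
#' before/after history is recorded.
#'
#' @param start_n Starting haploid chromosome number (positive integer).
#' @param events Character vector or list of events as described above.
#' @return Object of class \code{"karyotype_state"}: list with \code{n}
#'   (final haploid count) and \code{history} (data frame \code{event},
#'   \code{before}, \code{after}).
#' @examples
#' # ancestral n = 11: WGD, two fissions, then hybridization of two such
#' # n = 24 genomes gives the allotetraploid n = 48
#' apply_karyotype_events(11, c("WGD", "fission", "fission", "hybridize:24"))
#' @export
apply_karyotype_events <- function(start_n, events = list()) {
  if (!is.numeric(start_n) || start_n < 1 || start_n != round(start_n))
    stop("start_n must be a positive integer")
  n <- as.integer(start_n)
  if (is.character(events)) events <- as.list(events)
  hist_event <- character(0)
  hist_before <- integer(0)
  hist_after <- integer(0)
  for (ev in events) {
    if (is.character(ev) && grepl("^hybridize:", ev)) {
      ev <- list(type = "hybridize",
                 other_n = as.integer(sub("^hybridize:", "", ev)))
    }
    if (is.character(ev)) ev <- list(type = ev)
    before <- n
    n <- switch(ev$type,
      WGD = 2L * n,
      fission = n + 1L,
      fusion = {
        if (n <= 1L) stop("fusion at n = 1 is impossible")
        n - 1L
      },
      hybridize = {
        m <- as.integer(ev$other_n)
        if (is.na(m) || m < 1L) stop("hybridize requires other_n >= 1")
        n + m
      },
      stop("unknown event type: ", ev$type)
    )
    hist_event <- c(hist_event, ev$type)
    hist_before <- c(hist_before, before)
    hist_after <- c(hist_after, n)
  }
  structure(list(n = n,
                 history = data.frame(event = hist_event,
                                      before = hist_before,
                                      after = hist_after)),
            class = "karyotype_state")
}

#' @export
print.karyotype_state <- function(x, ...) {
  cat(sprintf("karyotype: haploid n = %d (2n = %d)\n", x$n, 2L * x$n))
  if (nrow(x$history)) {
    chain <- c(x$history$before[1], x$history$after)
    cat("  ", paste(chain, collapse = " -> "), "\n")
    cat("  events:", paste(x$history$event, collapse = ", "), "\n")
  }
  invisible(x)
}
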