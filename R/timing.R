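# Internally calibrated dating of WGD and genome-merger events.
#
# Under neutrality T = Ks / (2 mu). Calibrating mu at a known speciation
# time lets older events be dated either absolutely (via mu) or
# relatively, by scaling the speciation time with a ratio of Ks peaks or
# of TE-divergence crossing values. All reported times are in Mya; mu is
# in substitutions per site per year.

.YEARS_PER_MYA <- 1e6

#' Construct a time interval in Mya
#'
#' @param lower,upper Interval bounds in Mya, \code{0 < lower <= upper}.
#' @param point Optional point estimate in Mya. Deliberately not forced
#'   inside \code{[lower, upper]}: published point calibrations can sit
#'   anywhere within (or even outside) a published interval.
#' @return Object of class \code{"time_interval"}.
#' @export
time_interval <- function(lower, upper, point = NULL) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (!(lower > 0 && lower <= upper))
    stop("need 0 < lower <= upper")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 point = if (is.null(point)) NULL else as.numeric(point)),
            class = "time_interval")
}

#' @export
print.time_interval <- function(x, digits = 3, ...) {
  cat(sprintf("[%s, %s] Mya%s\n",
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              if (!is.null(x$point))
                sprintf(" (point %s)", format(x$point, digits = digits))
              else ""))
  invisible(x)
}

.scale_interval <- function(interval, r) {
  # dating is monotone in Ks/divergence, so endpoint mapping is exact
  time_interval(r * interval$lower, r * interval$upper,
                point = if (is.null(interval$point)) NULL
                        else r * interval$point)
}

#' Calibrate the neutral substitution rate
#'
#' From 2*mu = Ks_speciation / T_speciation: the Ks peak at a speciation
#' event of independently known age fixes the lineage rate mu.
#'
#' @param ks_speciation Ks at the speciation peak (> 0).
#' @param t_speciation_point Speciation time in Mya (> 0).
#' @return mu in substitutions per site per year.
#' @examples
#' calibrate_mu(0.05, 5.75)  # ~4.35e-9
#' @export
calibrate_mu <- function(ks_speciation, t_speciation_point) {
  if (!is.numeric(ks_speciation) || ks_speciation <= 0)
    stop("ks_speciation must be > 0")
  if (!is.numeric(t_speciation_point) || t_speciation_point <= 0)
    stop("t_speciation_point must be > 0")
  ks_speciation / (2 * t_speciation_point * .YEARS_PER_MYA)
}

#' Date an event from Ks and a substitution rate
#'
#' T = Ks / (2 mu), returned in Mya.
#'
#' @param ks Synonymous divergence (>= 0).
#' @param mu Substitution rate per site per year (> 0).
#' @return Time in Mya.
#' @export
date_from_ks <- function(ks, mu) {
  if (!is.numeric(ks) || any(ks < 0)) stop("ks must be >= 0")
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0")
  ks / (2 * mu) / .YEARS_PER_MYA
}

#' Date a WGD relative to a calibrated speciation
#'
#' T_WGD = (Ks_WGD / Ks_speciation) * T_speciation. With an interval
#' speciation time the interval is endpoint-mapped, which is exact
#' because the scaling is monotone.
#'
#' @param ks_wgd Ks at the WGD peak (> 0).
#' @param ks_speciation Ks at the speciation peak (> 0).
#' @param t_speciation A \code{\link{time_interval}} (or a single number
#'   in Mya, treated as a degenerate interval).
#' @return A \code{\link{time_interval}} for the WGD.
#' @examples
#' date_wgd_relative(0.35, 0.05, time_interval(3, 8))  # [21, 56] Mya
#' @export
date_wgd_relative <- function(ks_wgd, ks_speciation, t_speciation) {
  if (!is.numeric(ks_wgd) || ks_wgd <= 0) stop("ks_wgd must be > 0")
  if (!is.numeric(ks_speciation) || ks_speciation <= 0)
    stop("ks_speciation must be > 0")
  t_speciation <- .as_interval(t_speciation)
  .scale_interval(t_speciation, ks_wgd / ks_speciation)
}

#' Date the allopolyploid genome merger from TE divergence crossings
#'
#' T_merger = (D_merger / D_speciation) * T_speciation, with D_merger and
#' D_speciation the first and last intersection of the two subgenomes'
#' TE-divergence density curves (percent Kimura distance). The merger is
#' the more recent, lower-divergence crossing, so D_merger must not
#' exceed D_speciation; a violation means the crossings were mislabeled.
#'
#' @param d_merger First (low-divergence) crossing, percent.
#' @param d_speciation Last (high-divergence) crossing, percent.
#' @param t_speciation Speciation \code{\link{time_interval}}.
#' @return A \code{\link{time_interval}} for the merger.
#' @examples
#' date_merger_relative(6.3, 27.3, time_interval(3, 8))  # ~[0.69, 1.85]
#' @export
date_merger_relative <- function(d_merger, d_speciation, t_speciation) {
  if (!is.numeric(d_merger) || d_merger <= 0) stop("d_merger must be > 0")
  if (!is.numeric(d_speciation) || d_speciation <= 0)
    stop("d_speciation must be > 0")
  if (d_merger > d_speciation)
    stop("d_merger exceeds d_speciation: the merger must be the more ",
         "recent (lower-divergence) crossing; crossings appear mislabeled")
  t_speciation <- .as_interval(t_speciation)
  .scale_interval(t_speciation, d_merger / d_speciation)
}

.as_interval <- function(x) {
  if (inherits(x, "time_interval")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(time_interval(x, x))
  if (is.numeric(x) && length(x) == 2L) return(time_interval(x[1], x[2]))
  stop("expected a time_interval or a numeric of length 1 or 2")
}
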