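# 1-D Gaussian mixture fitting by EM with BIC model selection, used to
# locate the speciation and WGD peaks of a Ks distribution.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed",
                                envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.gmm_loglik <- function(x, w, mu, sigma) {
  dens <- vapply(seq_along(w),
                 function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                 numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(pmax(rowSums(dens), .Machine$double.xmin)))
}

.gmm_em <- function(x, k, init_mu, sd_floor, tol = 1e-6, max_iter = 500,
                    init = NULL, debug = FALSE) {
  n <- length(x)
  if (is.null(init)) {
    mu <- init_mu
    sigma <- rep(max(stats::sd(x) / k, sd_floor), k)
    w <- rep(1 / k, k)
  } else {
    mu <- init$means
    sigma <- init$sds
    w <- init$weights
  }
  ll <- -Inf
  dens <- matrix(0, nrow = n, ncol = k)
  for (iter in seq_len(max_iter)) {
    # E step (also yields the log-likelihood of the current parameters)
    for (j in seq_len(k))
      dens[, j] <- w[j] * stats::dnorm(x, mu[j], sigma[j])
    rs <- pmax(rowSums(dens), .Machine$double.xmin)
    ll_new <- sum(log(rs))
    # the sd floor can nudge the likelihood down by rounding; only a
    # genuine decrease is a bug, asserted in debug mode
    if (debug && is.finite(ll) && ll_new < ll - 1e-6 * abs(ll))
      stop("EM log-likelihood decreased")
    converged <- abs(ll_new - ll) < tol
    ll <- ll_new
    if (converged) break
    resp <- dens / rs
    # M step
    nk <- pmax(colSums(resp), .Machine$double.xmin)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
    sigma <- pmax(sigma, sd_floor)
  }
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], sds = sigma[ord],
       loglik = ll, iterations = iter)
}

#' Fit a 1-D Gaussian mixture to a Ks (or divergence) distribution
#'
#' Runs expectation-maximisation for each candidate component count with
#' k-means initialisation (10 restarts under a fixed master seed, best
#' log-likelihood wins) and selects the component count minimising BIC,
#' \eqn{-2\ell + p\log n} with \eqn{p = 3k - 1} free parameters. Ties in
#' BIC go to the smaller model. Values outside \code{[0, ks_cap]} are
#' discarded before fitting: saturated old paralogs destabilise EM and
#' carry no peak information.
#'
#' @param values Numeric vector of finite values (n >= 20 after capping).
#' @param k_candidates Candidate component counts, default \code{1:5}.
#' @param seed Master seed controlling k-means restarts.
#' @param ks_cap Upper truncation bound (default 3.0).
#' @param sd_floor Lower bound on component standard deviations,
#'   preventing variance collapse (default 1e-4).
#' @param n_restarts Number of k-means-initialised EM restarts per k.
#' @return Object of class \code{"mixture_fit"}: list with \code{k},
#'   \code{weights}, \code{means}, \code{sds}, \code{loglik}, \code{bic},
#'   \code{n}, \code{bic_by_k}.
#' @seealso \code{\link{extract_peaks}}
#' @export
fit_gmm <- function(values, k_candidates = 1:5, seed = 1, ks_cap = 3.0,
                    sd_floor = 1e-4, n_restarts = 10) {
  values <- values[is.finite(values)]
  values <- values[values >= 0 & values <= ks_cap]
  n <- length(values)
  if (n < 20) stop("need at least 20 finite values within [0, ks_cap]")
  if (length(unique(values)) == 1L) {
    warning("degenerate data: all values identical")
    fit <- list(k = 1L, weights = 1, means = values[1], sds = sd_floor,
                loglik = .gmm_loglik(values, 1, values[1], sd_floor),
                n = n)
    fit$bic <- -2 * fit$loglik + 2 * log(n)
    fit$bic_by_k <- stats::setNames(fit$bic, "1")
    return(structure(fit, class = "mixture_fit"))
  }
  best <- NULL
  bic_by_k <- stats::setNames(rep(NA_real_, length(k_candidates)),
                              k_candidates)
  for (k in k_candidates) {
    if (length(unique(values)) < k) next
    # short-run/long-run strategy: every restart gets a capped EM, only
    # the best restart is polished to full tolerance
    best_k <- NULL
    for (r in seq_len(n_restarts)) {
      init_mu <- .with_seed(seed + 10000L * k + r, {
        if (k == 1L) mean(values)
        else as.numeric(stats::kmeans(values, centers = k,
                                      nstart = 1)$centers)
      })
      em <- tryCatch(.gmm_em(values, k, sort(init_mu), sd_floor,
                             tol = 1e-4, max_iter = 60),
                     error = function(e) NULL)
      if (is.null(em)) next
      if (is.null(best_k) || em$loglik > best_k$loglik) best_k <- em
    }
    if (is.null(best_k)) next
    best_k <- .gmm_em(values, k, best_k$means, sd_floor, init = best_k)
    p <- 3 * k - 1
    bic <- -2 * best_k$loglik + p * log(n)
    bic_by_k[as.character(k)] <- bic
    # strict improvement required: ties favour the smaller model
    if (is.null(best) || bic < best$bic - 1e-9) {
      best <- c(best_k, list(k = as.integer(k), bic = bic))
    }
  }
  if (is.null(best)) stop("EM failed for every candidate k")
  structure(list(k = best$k, weights = best$weights, means = best$means,
                 sds = best$sds, loglik = best$loglik, bic = best$bic,
                 n = n, bic_by_k = bic_by_k),
            class = "mixture_fit")
}

#' Extract mixture peaks
#'
#' Returns the component means of a fitted mixture with weight at least
#' \code{min_weight}, sorted ascending: the candidate speciation / WGD
#' peak locations. Mapping peaks to biological events is the caller's
#' decision.
#'
#' @param fit A \code{\link{fit_gmm}} result.
#' @param min_weight Minimum component weight for a peak to be reported.
#' @return Data frame with columns \code{mean}, \code{weight}, \code{sd},
#'   one row per reported peak, sorted by mean.
#' @export
extract_peaks <- function(fit, min_weight = 0.05) {
  stopifnot(inherits(fit, "mixture_fit"))
  keep <- fit$weights >= min_weight
  out <- data.frame(mean = fit$means[keep], weight = fit$weights[keep],
                    sd = fit$sds[keep])
  out[order(out$mean), , drop = FALSE]
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: k = %d components, n = %d, BIC = %.1f\n",
              x$k, x$n, x$bic))
  comp <- data.frame(weight = round(x$weights, 3),
                     mean = round(x$means, 4),
                     sd = round(x$sds, 4))
  print(comp, row.names = TRUE)
  invisible(x)
}

#' @export
summary.mixture_fit <- function(object, ...) {
  cat(sprintf("Gaussian mixture (EM), n = %d\n", object$n))
  cat("BIC by candidate k:\n")
  print(round(object$bic_by_k, 1))
  cat(sprintf("selected k = %d (log-likelihood %.2f)\n",
              object$k, object$loglik))
  print.mixture_fit(object)
}

#' @export
logLik.mixture_fit <- function(object, ...) {
  structure(object$loglik, df = 3 * object$k - 1, nobs = object$n,
            class = "logLik")
}

#' Mixture density of a fitted model
#' @param fit A \code{\link{fit_gmm}} result.
#' @param x Points at which to evaluate the mixture density.
#' @return Numeric vector of densities.
#' @export
mixture_density <- function(fit, x) {
  stopifnot(inherits(fit, "mixture_fit"))
  rowSums(vapply(seq_len(fit$k),
                 function(j) fit$weights[j] *
                   stats::dnorm(x, fit$means[j], fit$sds[j]),
                 numeric(length(x))))
}

#' @export
plot.mixture_fit <- function(x, breaks = 50, main = "Ks distribution", ...) {
  stop_if_no_values <- x$n
  grid <- seq(min(x$means) - 4 * max(x$sds),
              max(x$means) + 4 * max(x$sds), length.out = 512)
  dens <- mixture_density(x, grid)
  plot(grid, dens, type = "l", lwd = 2, xlab = "value",
       ylab = "mixture density", main = main, ...)
  for (j in seq_len(x$k)) {
    graphics::lines(grid,
                    x$weights[j] * stats::dnorm(grid, x$means[j], x$sds[j]),
                    lty = 2)
  }
  graphics::abline(v = x$means, col = "grey60", lty = 3)
  invisible(x)
}
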