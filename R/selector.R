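# Multistep selection of lineage-discriminating orthogroups:
# z-score outlier screen -> phylogenetic-signal filter (Blomberg's K,
# Pagel's lambda) -> Welch's t screen -> recursive feature elimination
# under three classifiers, each reporting its top-ranked families.
#
# Gene-count rows are right-skewed, so counts are log1p-transformed
# before z-scores, signal statistics, Welch tests and classifier
# standardization.

.log_counts <- function(mat) log1p(mat)

#' Screen out single-carrier outlier orthogroups
#'
#' Computes per-orthogroup z-scores across species (on log1p counts,
#' using that row's mean and sd) and flags orthogroups whose extreme
#' values (z > \code{z_threshold}) are concentrated in at most
#' \code{max_carriers} species: families blown up in one or two taxa are
#' assembly or annotation artifacts rather than lineage signal.
#' Zero-variance rows have undefined z-scores and are retained (they
#' cannot be outliers).
#'
#' @param counts Integer matrix, orthogroups x species.
#' @param z_threshold z-score above which a species counts as a carrier.
#' @param max_carriers Maximum carrier count for a row to be flagged.
#' @return List with \code{retained} (submatrix) and \code{flagged}
#'   (character vector of removed orthogroup ids).
#' @export
zscore_outlier_screen <- function(counts, z_threshold = 3.0,
                                  max_carriers = 2) {
  stopifnot(is.matrix(counts), ncol(counts) >= 3)
  x <- .log_counts(counts)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  flagged <- logical(nrow(x))
  pos <- sdv > 0
  if (any(pos)) {
    z <- (x[pos, , drop = FALSE] - mu[pos]) / sdv[pos]
    carriers <- rowSums(z > z_threshold)
    flagged[pos] <- carriers >= 1 & carriers <= max_carriers
  }
  list(retained = counts[!flagged, , drop = FALSE],
       flagged = rownames(counts)[flagged])
}

#' Blomberg's K phylogenetic signal
#'
#' Ratio of the observed mean squared deviation from the phylogenetically
#' weighted mean (MSE0) over the GLS mean squared error under the tree
#' covariance (MSE), scaled by its expectation under Brownian motion,
#' \eqn{(\mathrm{tr}(C) - n/\mathbf{1}'C^{-1}\mathbf{1})/(n-1)}. K is
#' about 1 for Brownian traits, below 1 for traits with less signal than
#' Brownian motion.
#'
#' @param trait Named numeric vector; names must match the tree's tips.
#' @param tree A rooted \code{ape::phylo} with branch lengths.
#' @return K (numeric), or \code{NA} when the trait has zero variance.
#' @references Blomberg, Garland & Ives (2003) Evolution 57:717-745.
#' @export
blomberg_k <- function(trait, tree) {
  prep <- .align_trait(trait, tree)
  if (is.null(prep)) return(NA_real_)
  x <- prep$x
  C <- prep$C
  n <- length(x)
  Cinv <- solve(C)
  sum_cinv <- sum(Cinv)
  a <- sum(Cinv %*% x) / sum_cinv
  r <- x - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(t(r) %*% Cinv %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / sum_cinv) / (n - 1)
  (mse0 / mse) / expected
}

#' Pagel's lambda phylogenetic signal
#'
#' Maximum-likelihood estimate of the multiplier on the off-diagonal
#' entries of the phylogenetic covariance matrix: 0 means the trait
#' ignores the tree (star phylogeny), 1 means full Brownian covariance.
#' The GLS mean and Brownian rate are profiled analytically at each
#' candidate lambda; the 1-D likelihood is maximised over
#' \code{[0, lambda_max]} by bounded search with tolerance 1e-6.
#'
#' @inheritParams blomberg_k
#' @param lambda_max Upper bound of the search interval (default 1).
#' @return List with \code{lambda} and \code{loglik}, or \code{NA} fields
#'   when the trait has zero variance.
#' @export
pagel_lambda <- function(trait, tree, lambda_max = 1.0) {
  prep <- .align_trait(trait, tree)
  if (is.null(prep)) return(list(lambda = NA_real_, loglik = NA_real_))
  x <- prep$x
  C <- prep$C
  n <- length(x)
  offdiag <- C - diag(diag(C))
  ll_at <- function(lam) {
    Cl <- lam * offdiag + diag(diag(C))
    Cinv <- tryCatch(solve(Cl), error = function(e) NULL)
    if (is.null(Cinv)) return(-Inf)
    ld <- determinant(Cl, logarithm = TRUE)
    if (ld$sign <= 0) return(-Inf)
    a <- sum(Cinv %*% x) / sum(Cinv)
    r <- x - a
    s2 <- drop(t(r) %*% Cinv %*% r) / n
    if (s2 <= 0) return(-Inf)
    -0.5 * (n * log(2 * pi * s2) + as.numeric(ld$modulus) + n)
  }
  opt <- stats::optimize(ll_at, interval = c(0, lambda_max),
                         maximum = TRUE, tol = 1e-6)
  # bounded search can miss the endpoints; check them explicitly
  cand <- c(opt$maximum, 0, lambda_max)
  lls <- c(opt$objective, ll_at(0), ll_at(lambda_max))
  best <- which.max(lls)
  list(lambda = cand[best], loglik = lls[best])
}

.align_trait <- function(trait, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4) stop("need at least 4 tips")
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label))
      stop("unnamed trait must have one value per tip")
    names(trait) <- tree$tip.label
  }
  if (!setequal(names(trait), tree$tip.label))
    stop("trait names do not match tree tips")
  x <- trait[tree$tip.label]
  if (stats::sd(x) == 0) return(NULL)  # signal undefined
  C <- ape::vcv(tree)
  list(x = as.numeric(x), C = C[tree$tip.label, tree$tip.label])
}

#' Retain orthogroups with intermediate conservation signal
#'
#' Computes Blomberg's K and Pagel's lambda for each orthogroup's
#' (log1p) count profile and retains rows with K > \code{k_min} and
#' lambda > \code{lambda_min}. Rows with undefined signal (zero variance)
#' are dropped with a message, as are rows that are all-zero across the
#' species set.
#'
#' @param counts Integer matrix, orthogroups x species; column names must
#'   match the tree tips.
#' @param tree \code{ape::phylo} species tree.
#' @param k_min,lambda_min Retention thresholds (defaults 1.0 and 0.5).
#' @return List with \code{retained} (submatrix) and \code{stats} (data
#'   frame \code{orthogroup}, \code{blomberg_k}, \code{pagel_lambda},
#'   \code{defined}).
#' @export
signal_filter <- function(counts, tree, k_min = 1.0, lambda_min = 0.5) {
  stopifnot(is.matrix(counts))
  if (!setequal(colnames(counts), tree$tip.label))
    stop("count matrix species do not match tree tips")
  x <- .log_counts(counts)
  n_rows <- nrow(x)
  ks <- numeric(n_rows)
  lams <- numeric(n_rows)
  for (i in seq_len(n_rows)) {
    tr <- x[i, ]
    ks[i] <- blomberg_k(tr, tree)
    lams[i] <- if (is.na(ks[i])) NA_real_ else pagel_lambda(tr, tree)$lambda
  }
  stats_df <- data.frame(orthogroup = rownames(counts), blomberg_k = ks,
                         pagel_lambda = lams, defined = !is.na(ks))
  n_undef <- sum(is.na(ks))
  if (n_undef > 0)
    message(n_undef, " orthogroup(s) dropped: undefined signal (zero variance)")
  keep <- !is.na(ks) & ks > k_min & !is.na(lams) & lams > lambda_min
  retained <- counts[keep, , drop = FALSE]
  all_zero <- rowSums(retained) == 0
  if (any(all_zero)) {
    message(sum(all_zero), " orthogroup(s) dropped: zero counts in all species")
    retained <- retained[!all_zero, , drop = FALSE]
  }
  list(retained = retained, stats = stats_df)
}

.welch_row <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  va <- stats::var(xa); vb <- stats::var(xb)
  dm <- mean(xa) - mean(xb)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    # both classes constant: identical means carry no evidence
    if (dm == 0) return(c(t = 0, df = na + nb - 2, p = 1))
    return(c(t = sign(dm) * Inf, df = na + nb - 2, p = 0))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

#' Welch's t screen for differential copy number
#'
#' Two-sided Welch's t-test (unequal variances, Welch-Satterthwaite
#' degrees of freedom) on each orthogroup's log1p counts between the two
#' species classes, retaining rows with p below the (deliberately
#' relaxed) threshold \code{alpha}.
#'
#' @param counts Integer matrix, orthogroups x species.
#' @param labels Named character vector mapping each species (column) to
#'   class \code{"A"} or \code{"B"}.
#' @param alpha Retention threshold on the p-value (default 0.1).
#' @return List with \code{retained} (submatrix) and \code{tests} (data
#'   frame \code{orthogroup}, \code{t}, \code{df}, \code{p}).
#' @export
welch_screen <- function(counts, labels, alpha = 0.1) {
  stopifnot(is.matrix(counts))
  labels <- labels[colnames(counts)]
  if (any(is.na(labels))) stop("labels missing for some species")
  if (!all(labels %in% c("A", "B"))) stop("labels must be 'A' or 'B'")
  ia <- which(labels == "A")
  ib <- which(labels == "B")
  if (length(ia) < 2 || length(ib) < 2)
    stop("need at least 2 species per class")
  x <- .log_counts(counts)
  res <- t(apply(x, 1, function(row) .welch_row(row[ia], row[ib])))
  tests <- data.frame(orthogroup = rownames(counts), t = res[, "t"],
                      df = res[, "df"], p = res[, "p"], row.names = NULL)
  keep <- tests$p < alpha
  list(retained = counts[keep, , drop = FALSE], tests = tests)
}

.fit_importance <- function(X, y, classifier, seed) {
  p <- ncol(X)
  imp <- switch(classifier,
    "regularized-linear" = {
      # few samples per class is the operating regime here: the model is
      # a regularized ranking device, so glmnet's small-n warning is moot
      fit <- suppressWarnings(
        glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = 0.1, standardize = FALSE))
      abs(as.numeric(fit$beta))
    },
    "random-forest" = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(p))
      fit <- ranger::ranger(y = y, x = df, num.trees = 500,
                            importance = "impurity", seed = seed,
                            num.threads = 1)
      as.numeric(fit$variable.importance)
    },
    "gradient-boosted-trees" = {
      Xn <- X
      colnames(Xn) <- paste0("f", seq_len(p))
      fit <- xgboost::xgboost(Xn, y, nrounds = 50, max_depth = 2,
                              learning_rate = 0.3, nthreads = 1,
                              verbosity = 0)
      it <- xgboost::xgb.importance(model = fit)
      out <- stats::setNames(rep(0, p), colnames(Xn))
      out[it$Feature] <- it$Gain
      as.numeric(out)
    },
    stop("unknown classifier: ", classifier))
  imp
}

#' Recursive feature elimination ranking of orthogroups
#'
#' Treats species as samples and orthogroup (log1p, per-feature
#' standardized) counts as features, then iteratively fits the chosen
#' classifier, ranks features by absolute coefficient (regularized
#' logistic regression) or impurity/gain importance (tree ensembles), and
#' eliminates the weakest 10\% (at least one) per iteration until
#' \code{n_keep} features remain. With ~19 samples and hundreds of
#' features this is a ranking device under strong regularization, not a
#' predictive model.
#'
#' @param counts Integer matrix, orthogroups x species.
#' @param labels Named class vector as in \code{\link{welch_screen}}.
#' @param classifier One of \code{"regularized-linear"},
#'   \code{"random-forest"}, \code{"gradient-boosted-trees"}.
#' @param n_keep Number of features to retain (default 20).
#' @param seed Integer seed; results are deterministic given it.
#' @return Data frame \code{orthogroup}, \code{importance}, \code{rank},
#'   sorted by rank, with \code{min(n_keep, nrow(counts))} rows.
#' @export
rfe_rank <- function(counts, labels,
                     classifier = c("regularized-linear", "random-forest",
                                    "gradient-boosted-trees"),
                     n_keep = 20, seed = 1) {
  classifier <- match.arg(classifier)
  stopifnot(is.matrix(counts))
  labels <- labels[colnames(counts)]
  if (any(is.na(labels))) stop("labels missing for some species")
  y <- factor(labels, levels = c("A", "B"))
  if (any(table(y) == 0)) stop("both classes must be non-empty")
  if (nrow(counts) < n_keep)
    warning("fewer candidates than n_keep: returning all, ranked")
  X_full <- t(.log_counts(counts))
  # per-feature standardization; constant features get zero scale -> 0
  X_full <- apply(X_full, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  rownames(X_full) <- colnames(counts)
  feats <- rownames(counts)
  active <- seq_along(feats)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- length(active)
    imp <- .with_seed(seed + iter, {
      .fit_importance(X_full[, active, drop = FALSE], y, classifier,
                      seed = seed + iter)
    })
    if (p <= n_keep) break
    n_drop <- min(max(1L, floor(0.1 * p)), p - n_keep)
    # deterministic tie-break: among equal importance, drop later features
    ord <- order(imp, -seq_len(p))
    active <- sort(active[-ord[seq_len(n_drop)]])
  }
  ord <- order(-imp, seq_along(imp))
  data.frame(orthogroup = feats[active][ord],
             importance = imp[ord],
             rank = seq_along(ord), row.names = NULL)
}

#' Select lineage-discriminating orthogroups
#'
#' Composes the full multistep pipeline: z-score outlier screen,
#' phylogenetic-signal filter (K > 1, lambda > 0.5), Welch's t screen
#' (p < 0.1), then recursive feature elimination under each of the three
#' classifiers, designating each classifier's top \code{n_keep} ranked
#' orthogroups as lineage-associated families and reporting their union
#' with per-classifier provenance. If any stage empties the candidate
#' set, the report terminates at that stage with diagnostics rather than
#' raising.
#'
#' @param counts Integer matrix, orthogroups x species.
#' @param tree \code{ape::phylo} species tree whose tips are the species.
#' @param labels Named class vector (\code{"A"} = focal lineage,
#'   \code{"B"} = background) over the species.
#' @param config Optional list overriding \code{z_threshold},
#'   \code{max_carriers}, \code{k_min}, \code{lambda_min}, \code{alpha},
#'   \code{n_keep}, \code{seed}, \code{classifiers}.
#' @return Object of class \code{"selection_report"}.
#' @export
select_lineage_orthogroups <- function(counts, tree, labels,
                                       config = list()) {
  cfg <- utils::modifyList(list(
    z_threshold = 3.0, max_carriers = 2, k_min = 1.0, lambda_min = 0.5,
    alpha = 0.1, n_keep = 20, seed = 1,
    classifiers = c("regularized-linear", "random-forest",
                    "gradient-boosted-trees")), config)
  stage_counts <- c(input = nrow(counts))
  report <- list(config = cfg, stage_counts = stage_counts,
                 terminated_at = NULL, rankings = list(),
                 union = NULL)
  class(report) <- "selection_report"

  z <- zscore_outlier_screen(counts, cfg$z_threshold, cfg$max_carriers)
  report$flagged_outliers <- z$flagged
  report$stage_counts <- c(report$stage_counts,
                           outlier_screen = nrow(z$retained))
  if (nrow(z$retained) == 0) {
    report$terminated_at <- "outlier_screen"
    return(report)
  }

  sig <- signal_filter(z$retained, tree, cfg$k_min, cfg$lambda_min)
  report$signal_stats <- sig$stats
  report$stage_counts <- c(report$stage_counts,
                           signal_filter = nrow(sig$retained))
  if (nrow(sig$retained) == 0) {
    report$terminated_at <- "signal_filter"
    return(report)
  }

  w <- welch_screen(sig$retained, labels, cfg$alpha)
  report$welch_tests <- w$tests
  report$stage_counts <- c(report$stage_counts,
                           welch_screen = nrow(w$retained))
  if (nrow(w$retained) == 0) {
    report$terminated_at <- "welch_screen"
    return(report)
  }

  for (cl in cfg$classifiers) {
    report$rankings[[cl]] <- rfe_rank(w$retained, labels, cl,
                                      n_keep = cfg$n_keep, seed = cfg$seed)
  }
  top_lists <- lapply(report$rankings, function(r)
    utils::head(r$orthogroup, cfg$n_keep))
  union_ids <- sort(unique(unlist(top_lists)))
  prov <- vapply(union_ids, function(id)
    paste(names(top_lists)[vapply(top_lists, function(l) id %in% l,
                                  logical(1))], collapse = ";"),
    character(1))
  report$union <- data.frame(orthogroup = union_ids, classifiers = prov,
                             row.names = NULL)
  report
}

#' @export
print.selection_report <- function(x, ...) {
  cat("lineage-orthogroup selection report\n")
  cat("  stage survivor counts:\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("    %-15s %d\n", nm, x$stage_counts[[nm]]))
  if (!is.null(x$terminated_at)) {
    cat("  pipeline terminated at stage:", x$terminated_at, "\n")
    return(invisible(x))
  }
  for (cl in names(x$rankings))
    cat(sprintf("  %s: top %d of %d candidates\n", cl,
                min(x$config$n_keep, nrow(x$rankings[[cl]])),
                x$stage_counts[["welch_screen"]]))
  cat(sprintf("  union of top lists: %d orthogroups\n", nrow(x$union)))
  invisible(x)
}

#' @export
summary.selection_report <- function(object, ...) {
  print(object)
  if (!is.null(object$union)) {
    cat("\nunion with provenance:\n")
    print(object$union, row.names = FALSE)
  }
  invisible(object)
}
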