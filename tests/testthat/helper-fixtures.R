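# Shared fixtures built in code.

balanced_tree <- function(n_tips, brlen = 1) {
  ape::compute.brlen(ape::stree(n_tips, "balanced"), brlen)
}

# draw one Brownian trait on a tree (unit-depth-normalised covariance)
bm_trait <- function(tree, sd = 1) {
  C <- ape::vcv(tree)
  C <- C / max(diag(C))
  U <- chol(C)
  stats::setNames(sd * drop(t(U) %*% stats::rnorm(nrow(C))),
                  tree$tip.label)
}

# two-crossing TE scenario: SG1 unimodal, SG2 bimodal straddling it
two_crossing_te_spec <- function(n = 4000) {
  list(
    sg1 = list(label = "SG1", n_copies = n, weights = 1,
               means = 18, sds = 5),
    sg2 = list(label = "SG2", n_copies = n, weights = c(0.5, 0.5),
               means = c(6, 30), sds = c(2.5, 4))
  )
}

acanthus_class_a <- c("Ail", "Aeb", "SG1", "SG2")
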