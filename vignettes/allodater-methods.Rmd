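---
title: "Dating polyploidy and hybridization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating polyploidy and hybridization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models,
the parameters that matter, the numerical choices, and the limits of
what the synthetic-data test suites demonstrate.

## 1. Internally calibrated dating

All dating in this package rests on the neutral approximation that
synonymous divergence accumulates linearly in time, `Ks = 2 mu T`. The
package deliberately avoids estimating `mu` from external data: a
speciation event of independently known age whose Ks peak is visible in
the same distributions calibrates the rate internally
(`calibrate_mu()`), and older events are dated either through that rate
(`date_from_ks()`) or — avoiding `mu` entirely — by the peak ratio
(`date_wgd_relative()`). Ratio dating assumes the two events share one
lineage rate; it propagates an interval calibration by endpoint
mapping, which is exact because the transform is monotone, but it
deliberately offers no confidence statement beyond that interval.

The genome-merger clock for an allopolyploid uses the same ratio logic
on the TE divergence scale (`date_merger_relative()`). The two
subgenomes' TE copies diverged under their progenitors' separate
genomic environments between speciation and merger, and under the
shared environment afterwards; the last intersection of the two
Kimura-distance density curves marks the speciation-era divergence
level `D_speciation`, the first intersection the merger level
`D_merger`. Treating the TE divergence scale as proportional to time
between those anchors is a stronger assumption than the Ks clock — TE
landscapes are shaped by insertion/deletion dynamics as well as
substitution — and the result should be read as a consistency check on
an order-of-magnitude, not a precise date.

Calibration conventions: times are handled in Mya throughout and `mu`
in substitutions/site/year (the 10^6 conversion is fixed internally).
Interval inputs accept a separate point calibration because published
point values need not be interval midpoints (`time_interval(3, 8,
point = 5.75)`); the point value drives `calibrate_mu()`, the interval
drives ratio dating. Reported intervals are rounded only at the
reporting layer (WGD dating to integers, merger dating to one decimal,
matching the precision such intervals are usually quoted with); nothing
is rounded internally.

## 2. NG86 substitution counting

`estimate_ks_ka()` implements Nei–Gojobori (1986) counting rather than
an ML codon model: per-codon synonymous site fractions (mutations to
stop codons count as nonsynonymous, so site fractions sum to exactly 3
per codon), pathway averaging for multi-hit codons over all minimal
substitution orderings that avoid stop codons (codons whose every
pathway is blocked are dropped), and Jukes–Cantor correction
`d = -(3/4) log(1 - 4p/3)`. A proportion at or beyond 0.74 is flagged
saturated and yields `NA` rather than an error, because genuine Ks
distributions contain saturated old paralogs and must tolerate them.
NG86 is fully specifiable and auditable — the test suite checks it
codon-by-codon against an independent brute-force enumeration — at the
cost of a small systematic difference from ML estimators (yn00-style)
on real data; peak *positions*, which are what the dating consumes,
shift only slightly between the two. All 64x64 codon-pair difference
counts and site fractions are precomputed once per session, so
estimation is table lookup and scales to genome-sized pair lists.

Tandem filtering (`filter_tandem_pairs()`): a pair is excluded when
both genes share a chromosome and the *gap between their intervals*
(overlap counts as zero) is under 200 bp. Gap distance, rather than
start-to-start distance, is the reading adopted for "within 200 bp":
it is the only interpretation that is invariant to gene length. The
threshold is exposed as `max_gap_bp`.

## 3. Gaussian mixtures and density intersections

`fit_gmm()` fits 1-D Gaussian mixtures by EM for each candidate `k`
(default 1–5) and selects `k` by BIC with `p = 3k - 1` free parameters;
BIC ties break toward the smaller model. Numerical choices:

* values outside `[0, ks_cap]` (default cap 3.0) are discarded before
  fitting — saturated paralogs destabilize EM and carry no peak
  information;
* initialisation is k-means under a fixed master seed, 10 restarts per
  `k`; every restart runs a capped EM (60 iterations, tolerance 1e-4)
  and only the best restart is polished to the full tolerance (1e-6 on
  the log-likelihood, at most 500 iterations) — the standard
  short-run/long-run strategy for multimodal likelihoods;
* component standard deviations are floored at 1e-4 to prevent the
  classical EM variance collapse; a constant input degenerates
  gracefully to a single component at that constant with a warning;
* the monotone-likelihood property of EM is asserted in debug mode
  (`.gmm_em(..., debug = TRUE)`), not in production, where the sd floor
  can cause sub-tolerance wiggles.

Peak-to-event assignment is *not* inferred: `extract_peaks()` returns
the component means above a weight floor (default 0.05) in ascending
order, and the caller decides which peak anchors which event. This is a
deliberate boundary — on real data the assignment requires biological
context (orthologous vs paralogous comparisons) that no univariate fit
contains.

`kde()` wraps the classical Gaussian-kernel estimate with Silverman's
bandwidth `0.9 min(sd, IQR/1.34) n^{-1/5}` on a 512-point grid spanning
the data ± 3 bandwidths. `curve_intersections()` resamples both curves
by linear interpolation onto a shared fine grid, locates sign changes
of the difference, refines each by bisection to 1/100 of the grid step,
and discards crossings where both densities are below 1e-4 — crossings
are meaningful in the bulk of TE divergence curves, not in their tails.
"No robust crossing" is an explicit result object, never a silent zero,
because downstream dating must not receive fabricated anchors.

## 4. Retention tracks and karyotype arithmetic

`retention_track()` slides a 100-gene window in 50-gene steps (defaults
exposed; gene-index windows rather than bp, so repeat-dense regions do
not distort the track) and reports the fraction of window genes
attributable to each progenitor source label. Genes with no assignment
stay in the denominator as "unassigned": a chromosomal region that
lost its collinearity signal then shows up as a window whose labelled
ratios sum well below 1, which is exactly the signature worth
inspecting. The final partial window keeps its own denominator.

`apply_karyotype_events()` is deliberately elementary — WGD doubles,
fission adds one, fusion removes one, hybridization adds the partner's
count — with a recorded before/after history. Its value is not the
arithmetic but the executable, testable statement of a proposed
karyotype history (e.g. 11 → 22 → 23 → 24 → 48 for an allotetraploid
formed by two n = 24 progenitors descending from an n = 11 ancestor).

## 5. The lineage selector

`select_lineage_orthogroups()` composes four stages, each exposed on
its own:

1. **z-score outlier screen.** Counts are log1p-transformed (family
   sizes are right-skewed; the transform choice is exposed by using the
   exported stage functions directly if raw-scale screening is wanted).
   A row is discarded when its `z > 3` carriers number one or two —
   single-species blowups are assembly/annotation artifacts, not
   lineage signal. Note an arithmetic constraint: a lone carrier can
   reach at most `z = (n-1)/sqrt(n)`, so the rule only operates on
   panels of a dozen or more species; on small panels it passes
   everything, harmlessly.
2. **Phylogenetic-signal filter.** Blomberg's K (ratio of observed to
   Brownian-expected MSE ratio, computed from the tree covariance
   matrix) and Pagel's lambda (ML multiplier on the off-diagonal
   covariance, profiled analytically over mean and rate, maximized over
   [0, 1] by bounded search at tolerance 1e-6 with explicit endpoint
   checks). Rows are kept when `K > 1` **and** `lambda > 0.5`. The
   thresholds are applied literally as stated even though `K > 1`
   conventionally means *strong* signal rather than "intermediate";
   both are config-exposed. `lambda_max = 1` (not the tree-dependent
   bound some implementations allow) because the threshold only needs
   [0, 1]. Zero-variance rows have undefined signal and are dropped
   with a logged count, as are all-zero rows.
3. **Welch screen.** Two-sided Welch t-test with Welch–Satterthwaite
   degrees of freedom on log1p counts, retained at the deliberately
   relaxed `P < 0.1`. The statistic is computed from the textbook
   formulas rather than `t.test()` so that zero-variance rows take
   defined values (`p = 1` for identical constant classes, `p = 0` for
   separated constant classes) instead of erroring; `t.test()` is the
   cross-check oracle in the test suite.
4. **Recursive feature elimination** under three classifiers — ridge
   logistic regression (glmnet, fixed `lambda = 0.1`,
   importance = |coefficient|), random forest (ranger, 500 trees,
   impurity importance), gradient boosting (xgboost, 50 rounds, depth
   2, importance = gain) — eliminating the weakest 10% (at least one)
   per iteration down to `n_keep = 20`, then ranking survivors by
   final-model importance with deterministic tie-breaks. With ~19
   samples and hundreds of features these are ranking devices under
   strong regularization, not predictive models, and no held-out
   evaluation is reported — which is also why each classifier's top-20
   list and the union with provenance are reported side by side rather
   than a single fused ranking.

Any stage that empties the candidate set terminates the report with
diagnostics instead of raising: a run that filters everything away is a
scientific result, not a crash.

## 6. What the synthetic-data generator emulates — and what it does not

Every generator is a pure function of its arguments and seed.

* `simulate_codon_pair()` plants synonymous/nonsynonymous divergence by
  rejection-sampled single-nucleotide codon edits at distinct sites,
  never creating stops, with each edit required to move the
  pathway-averaged NG86 counts relative to the *ancestral* codon by
  exactly +1 in its own class (sequential within-codon edits can
  otherwise open mixed pathways that leak between classes — with the
  constraint, a synonymous-only simulation yields `Ka = 0` exactly).
  Edit counts are Poisson with mean `p * sites` where
  `p = (3/4)(1 - exp(-4K/3))` is the difference proportion a
  Jukes–Cantor process at divergence `K` produces, so the estimator's
  JC correction is unbiased by construction. What remains unmodelled:
  indels, codon-usage bias, selection, transition/transversion bias —
  recovery results on this generator validate the counting and
  correction arithmetic, not robustness to real evolutionary
  heterogeneity.
* `simulate_te_profiles()` draws divergence values directly in percent
  space from normal mixtures truncated to [0, 100] and returns the
  *analytic* crossing points of the true mixture densities as truth —
  the KDE + intersection pipeline is then tested against values it has
  no access to. Real TE landscapes are not Gaussian mixtures; what the
  recovery shows is that the intersection machinery finds crossings to
  within a few tenths of a percent when crossings exist.
* `simulate_collinear_dataset()` wires codon-pair simulation to a
  planted Ks mixture, lays tandem pairs on a shared chromosome at a
  50-bp gap, and records a per-pair truth table, giving the
  ks → peaks → dating chain an end-to-end fixture.
* `simulate_count_matrix()` evolves a latent value by Brownian motion
  on the tree (covariance normalised to unit depth, so `bm_sd` is the
  root-to-tip latent SD), adds iid noise, and maps through
  `Poisson(exp(latent))` — the phylogenetic signal the K/lambda filters
  measure is therefore real, not cosmetic. Planted rows receive a
  latent-scale (log) shift on the focal-clade tips: a lineage-specific
  family expansion is a fold change, and on the log scale it is exactly
  the clade-structured pattern the signal filter should retain.
  Defaults (`base_mean = 20`, `bm_sd = 1`, `noise = 0.2`) put Poisson
  sampling noise well below the Brownian spread; with low-count
  families the Poisson noise acts as anti-phylogenetic white noise and
  the `K > 1` filter becomes nearly unsatisfiable for any row — a
  property of the statistic, documented here so users screening
  low-count matrices know to expect it.
* The bundled `example_species_tree()` (19 tips, four-tip focal clade)
  gives the focal clade the long-stem/recent-crown shape real
  allopolyploid complexes have. This matters: a clade-wide shift across
  a *short* stem is anti-Brownian (a burst), and Blomberg's K then
  *rejects* strongly shifted families; across a long stem the same
  shift is Brownian-plausible and K retains them.

Recovery-suite problem sizes (chosen as a balance of statistical
resolution against a test suite that runs in minutes, and stated here
as the package's own convention): Ks recovery at 2,000 codons over 50
seeds per target; mixture recovery at 2,000 draws over 50 replicates;
Blomberg's K under Brownian motion at 500 replicates on a 16-tip
balanced tree; Pagel's lambda at 200 replicates on a 32-tip tree (at 16
tips the ML estimate of lambda is noticeably downward-dispersed — a
known small-sample property, not an implementation defect); selector
recovery at 200 orthogroups (400 for the top-20 contract check, so the
post-filter candidate pool comfortably exceeds 20) with 5 planted
families at a 6-latent-unit shift.

## 7. Interfaces

The package's interface is its exported functions plus
`scripts/acceptance.R`; no shell CLI is shipped, since the intended
users drive analyses from R and every stage is a plain function over
data frames and matrices. File formats: FASTA via Biostrings; a
bespoke three-column collinearity TSV (`block_id`, `gene_a`, `gene_b`)
in place of aligner-specific block formats, which are under-documented
dialects; GFF3-lite (gene rows with `ID` and optional `source_label`
attributes; 1-based inclusive on disk, 0-based half-open in memory — the
boundary conversion lives entirely in the readers/writers); count
matrices and divergence tables as TSV; trees as Newick via ape. Strand
is parsed and preserved but ignored by all computations, none of which
are strand-dependent.

## 8. Known limitations

* The Ks clock inherits every caveat of neutral-rate constancy; the
  ratio form removes `mu` but not rate variation between the compared
  events' lineages.
* NG86 with JC correction undercounts relative to ML codon models at
  high divergence; distributions are capped at Ks 3 by default and
  saturated pairs are flagged, but peaks beyond ~1.5 should be treated
  as qualitative.
* The TE merger clock assumes the divergence scale is comparable across
  subgenomes and anchored by the same speciation event; lineage-specific
  TE activity violates this silently.
* Blomberg's K and Pagel's lambda are computed per orthogroup
  independently; no correction is applied for selecting on them, which
  is acceptable for a screening stage but means the retained set is not
  an inferential statement.
* The selector's classifiers are fit on very few samples by design;
  their rankings are stable under the fixed seed but should be read as
  prioritization, not classification accuracy.
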