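# allodater

Dating whole-genome duplication (WGD) and allopolyploid hybridization
events from synonymous divergence (Ks) and transposable-element (TE)
divergence landscapes, with companion tools for subgenome gene
retention, karyotype evolution, and machine-learning selection of
lineage-discriminating gene families.

The package is written for comparative genomicists working on recently
formed allopolyploids — the motivating system is a mangrove shrub whose
2n = 96 genome merges two 2n = 48 progenitor genomes — but every
component takes ordinary inputs (aligned CDS pairs, collinearity tables,
GFF3 gene coordinates, TE divergence values, orthogroup count matrices,
Newick trees) and can be applied to any plant polyploid.

## The model

Under neutrality, the synonymous divergence of a gene pair grows with
time as `Ks = 2 mu T`, with `mu` the substitution rate per site per
year. A speciation event of independently known age `T_sp` whose Ks peak
sits at `Ks_sp` therefore calibrates the lineage rate,

```
mu = Ks_sp / (2 T_sp)
```

and any older event leaving a Ks peak at `Ks_ev` can be dated either
absolutely (`T = Ks_ev / (2 mu)`) or relatively,

```
T_ev = (Ks_ev / Ks_sp) * T_sp ,
```

which endpoint-maps an interval calibration. An analogous ratio dates
the allopolyploid genome merger from the TE divergence scale: the two
subgenomes' TE Kimura-distance density curves first separate at the
progenitor speciation (`D_sp`, their last intersection) and converge
again below the merger point (`D_m`, their first intersection), giving
`T_merger = (D_m / D_sp) * T_sp`.

Supporting machinery, all implemented here: NG86 (Nei–Gojobori) counting
of synonymous/nonsynonymous sites and differences with stop-avoiding
pathway averaging and Jukes–Cantor correction; a 200-bp tandem-proximity
filter for collinear gene pairs; 1-D Gaussian mixture fitting by EM with
BIC model selection to locate Ks peaks; Kimura 2-parameter distances and
kernel-density intersection finding; windowed progenitor gene-retention
tracks; karyotype event arithmetic (WGD, fission, fusion,
hybridization); and a lineage-selector pipeline (z-score outlier screen,
Blomberg's K > 1 and Pagel's lambda > 0.5 phylogenetic-signal filter,
Welch's t screen at P < 0.1, recursive feature elimination under ridge
logistic regression, random forest, and gradient boosting, each
designating its top 20 orthogroups).

A seed-deterministic synthetic-data generator (`simulate_*` functions)
produces inputs with known truth — planted Ks mixtures, tandem pairs,
TE crossing points, Brownian count matrices with lineage-shifted
orthogroups — so the whole pipeline is testable without sequencing
data.

## Worked example

Simulate 400 collinear gene pairs whose true Ks values come from a
60/40 mixture at 0.05 (speciation) and 0.35 (WGD), with 5% planted
tandem pairs; estimate Ks, filter, fit the mixture, and date the WGD:

```r
library(allodater)

sim <- simulate_collinear_dataset(
  mixture_spec = data.frame(weight = c(0.6, 0.4),
                            mean = c(0.05, 0.35),
                            sd = c(0.02, 0.05)),
  n_pairs = 400, tandem_fraction = 0.05, seed = 1, n_codons = 300)

pairs <- ks_for_blocks(sim$blocks, sim$cds)
pairs <- filter_tandem_pairs(pairs, sim$features)
dist <- build_ks_distribution(pairs)
dist
#> Ks distribution: 380 retained pairs in 80 blocks (0 blocks dropped)
#>   pair Ks quartiles: 0.042 / 0.072 / 0.313

fit <- fit_gmm(dist$pair_values, seed = 1)
fit
#> Gaussian mixture fit: k = 2 components, n = 380, BIC = -859.4
#>   weight   mean     sd
#> 1  0.629 0.0495 0.0257
#> 2  0.371 0.3518 0.0799

peaks <- extract_peaks(fit)
mu <- calibrate_mu(peaks$mean[1], 5.75)
signif(mu, 3)
#> [1] 4.3e-09
date_wgd_relative(peaks$mean[2], peaks$mean[1], time_interval(3, 8))
#> [21.3, 56.9] Mya
```

The 20 planted tandem pairs are exactly the ones removed (380 of 400
retained), both mixture means are recovered to the third decimal, and
the dating reproduces the calibration arithmetic: with the published
peak values 0.35 and 0.05 the WGD interval is exactly 21–56 Mya.

Dating the genome merger from TE divergence profiles works the same
way through the density-curve intersections:

```r
cr <- curve_intersections(kde(sg1_divergences), kde(sg2_divergences))
date_merger_relative(cr$first, cr$last, time_interval(3, 8))
```

and with the published crossing values 6.3 and 27.3 gives 0.7–1.8 Mya.
The karyotype model reproduces the chromosome-number chain of an
allotetraploid's history:

```r
apply_karyotype_events(11, c("WGD", "fission", "fission", "hybridize:24"))
#> karyotype: haploid n = 48 (2n = 96)
#>    11 -> 22 -> 23 -> 24 -> 48
```

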