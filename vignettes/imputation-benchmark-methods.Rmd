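---
title: "Benchmarking marker imputation in inbred panels: models and methods"
author: "InbredImpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking marker imputation in inbred panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

InbredImpute reconstructs, on synthetic data, a complete imputation study
of the kind run on elite inbred crop panels genotyped with nested SNP
arrays: simulate a structured panel, hide genotypes under two missingness
designs, impute with map-independent and map-dependent algorithms, and
measure the downstream consequences for diversity estimation (Rogers'
distance), genomic prediction (RR-BLUP/GBLUP) and association-mapping
power (kinship-corrected mixed-model scans). The emulated study system is
a panel of 371 fully inbred European wheat varieties with 9,926 mapped
SNPs on 21 chromosomes (~4,500 cM), of which 1,573 form a nested
low-density array. All genotypes are haploid-equivalent 0/1 calls:
inbreds carry two identical alleles, so no heterozygote code exists in
the containers, and heterozygous codes in imported files are converted to
missing with a warning.

# The synthetic panel generator

`simulatePanel()` builds each line as a mosaic of `nFounders` founder
haplotypes. Two processes shape linkage disequilibrium:

* **Founder-pattern blocks.** Along each chromosome the founder allele
  pattern is *redrawn* with per-cM intensity `founderBlockRate`
  (probability `1 - exp(-rate * d)` across a gap of `d` cM) and otherwise
  persists. Markers inside one block share a single founder pattern and
  sit in near-complete LD; markers in different blocks are essentially
  uncorrelated. This produces the strongly bimodal adjacent-locus
  r-squared distribution characteristic of array data on elite panels
  (many pairs near 1, many near 0).
* **Line mosaics.** Each line copies one founder and switches to a
  uniformly drawn founder across a gap of `d` cM with probability
  `1 - exp(-mosaicSwitchRate * d)`. Per-cell mutation flips alleles with
  probability `mutationRate`.

Fresh founder patterns draw their allele frequency from a symmetric
Beta(`founderAfShape`, `founderAfShape`) and are rejection-sampled to be
polymorphic among the founders. Markers whose realized panel MAF falls
below `mafFloor` (default 0.01) have their pattern redrawn in a bounded
number of rounds, so the final panel holds exactly `nMarkers` polymorphic
markers with no missing calls.

## Calibration

The defaults (`nFounders = 100`, `founderAfShape = 0.05`,
`founderBlockRate = 0.32`, `mosaicSwitchRate = 0.005`,
`mutationRate = 1e-4`) were calibrated once so that a default panel
reproduces the two summary statistics of the emulated panel: mean
adjacent-locus r-squared about 0.52 and mean MAF about 0.13. Two
analytical constraints drove the choices:

* Mean adjacent r-squared is essentially the probability that two
  adjacent markers share a founder block, `E[exp(-blockRate * d)]`, plus
  a small chance-LD term; `founderBlockRate = 0.32` places it near 0.52
  at the default ~2.25 cM spacing.
* Under any symmetric Beta frequency law, conditioning on the MAF floor
  of 0.01 bounds the attainable mean MAF near 0.15 (the conditional
  density behaves like 1/p on [0.01, 0.5]); small `founderAfShape` and
  many founders approach that bound. The realized default is ~0.152 —
  inside the calibration band, though the floor prevents reaching 0.13
  exactly. A markedly U-shaped spectrum with a heavier rare tail would
  require either a lower floor or a non-Beta frequency law.

Marker positions are uniform per chromosome (the emulated study reports
no marker-density map, so uniform placement is an explicit assumption,
not an inference), and markers are split as evenly as possible across
chromosomes.

## What the generator does not emulate

Ascertainment bias of array design, pedigree structure, population
subdivision with migration, and non-random (restriction-site-correlated)
GBS missingness are all outside the model. Passing benchmarks on these
panels therefore demonstrates the *relative* behavior of the algorithms
under realistic LD and allele-frequency profiles, not their absolute
accuracy on any real data set.

# Masking designs

`maskLowToHigh()` partitions lines uniformly at random into a reference
population (full density) and a test population (low density only); all
imputeSet cells of test lines become evaluation targets. The expected
overall missing fraction is `((n - ref)/n) * (impute/high)`, which for
the emulated dimensions gives the canonical 72.8/61.5/38.8/16.1% levels
at reference sizes 50/100/200/300. `maskGbsLike()` masks an exact
per-line count `round(rate * nMarkers)` drawn uniformly without
replacement — per-line exact counts (rather than per-cell Bernoulli)
pin the realized level; this choice is deliberate where the emulated
procedure is ambiguous. Cells missing in the input are tracked as a
third state and are never evaluation targets.

# Imputation algorithms

* **Frequency baseline** (`imputeFreq`): each missing cell receives the
  marker's observed allele-1 frequency; also the initializer and
  fallback for the other algorithms.
* **Iterative Random Forest** (`imputeRandomForest`): markers sorted by
  ascending missingness; missing cells initialized by Bernoulli draws at
  the observed frequency; per iteration and marker, 100 regression trees
  (via `ranger`, single-threaded for determinism) trained on observed
  lines with all other markers' current values as predictors and
  `sqrt(nMarkers - 1)` candidates per split; ensemble means replace the
  missing cells. Iteration stops when the sum of squared dosage changes
  falls below tolerance, begins to increase (previous iterate kept), or
  after 10 rounds.
* **Shrinking-window matcher** (`imputeWindow`): windows of size 64, 32,
  ..., 4 markers slide with 50% overlap; donors fully observed in a
  window that agree with the target at every observed position vote for
  their allele at the target's missing cells, weighted by window size so
  long shared segments (evidence of a recent common ancestor) dominate;
  dosage is the weighted vote share, with frequency fallback for
  zero-vote cells.
* **Li–Stephens HMM** (`imputeLsHmm`): haploid copying model per
  chromosome; hidden state is the reference haplotype index, transitions
  keep the current reference with probability `exp(-c d)` plus the
  uniform share, emissions are `1 - eps` on match and `eps` on mismatch,
  missing sites emit uninformatively. Posteriors come from a scaled
  forward–backward pass (scaled arithmetic throughout; forward and
  backward total likelihoods agree to < 1e-8 relative), and dosages are
  posterior-weighted reference alleles. References are the lines fully
  observed on the chromosome, so the algorithm declines GBS-like panels
  (no fully observed line) with advice to use the window matcher — a
  deliberate contract rather than a limitation of forward–backward.

Defaults `eps = 0.01` and `c = 0.02`/cM suit the long founder segments
of the simulated panels (switch intensity near the mosaic's own scale);
`c` is exposed for panels with faster LD decay. Dosages are continuous
in [0, 1] and are *not* rounded before accuracy evaluation; rounding at
0.5 happens only where allele calls are required (Rogers' distance,
genotype export).

# Evaluation

Accuracy is the per-marker Pearson correlation between truth and dosage
over that marker's masked cells, averaged over markers with defined
correlations; zero-variance markers are excluded with an explicit count
rather than imputed as zero, since silent zeros would bias scenario
comparisons. The frequency baseline's constant dosages make its
correlation undefined everywhere; ordering comparisons score it 0. LD
stratification uses the maximum r-squared between an imputed marker and
any low-density marker within ±5 cM (window configurable; the emulated
procedure names no window). r-squared itself is `D^2 / (pA pa pB pb)`
with haplotype frequencies counted directly — inbred lines are phased
haplotypes. The squared numerator is used deliberately: the unsquared
form sometimes printed in the literature is not an r-squared and can go
negative.

# Rogers' distance and kinship

For inbred 0/1 calls Rogers' distance reduces to the proportion of
differing loci, which keeps it linearly related to the coefficient of
co-ancestry for homozygous lines; with pairwise-complete handling each
pair drops loci missing in either line and normalizes by its own locus
count (the treatment for non-imputed GBS data). Distance-matrix
agreement is the Pearson correlation of strict upper triangles, tested
by a one-sided Mantel permutation test with
`p = (hits + 1)/(nPerm + 1)`, default 999 permutations.

# Genomic prediction and association mapping

Phenotypes follow an additive model with equal per-marker variance
shares: `beta_i = s_i sqrt(sigmaG2/(m v_i))`, genetic values centered
and rescaled so the sample variance equals `sigmaG2` exactly — marginal
contributions are defined per marker, then the total is rescaled because
inter-marker LD would otherwise inflate the realized variance — and
residuals sized for heritability 0.91. QTL phenotypes give one marker
(MAF > 0.3, optionally in a target LD class relative to the typed
markers) 10% of the genetic variance and split the remainder equally;
because QTL and background are computed on the same panel, their sample
covariance makes the realized share fluctuate a little around 10%.

REML uses the spectral decomposition of the relationship matrix and a
bounded scalar search on the log variance ratio — exact for a single
genetic variance component. RR-BLUP solves the marker-space ridge
system; GBLUP the equivalent animal-model system on `G = W W'/c` with
`c` the sum of marker variances (diagonal mean ~1); the two agree to
1e-6 on shared coding, and the test suite keeps both routes so the
equivalence is checked rather than assumed. Indefinite kinships
(1 - Rogers' distance is not guaranteed PSD) receive a minimal diagonal
shift; eigenvalues within 1e-8 of zero are clamped without perturbing
the matrix.

The association scan fits `y = mu + alpha m + g + e` with
`g ~ N(0, 2 K sigmaG2)`, `K = 1 - RD` (the 2K scaling is retained from
the model statement; it is absorbed into the variance component and does
not affect tests). The variance ratio is estimated once under the null
and reused for every marker — the standard
population-parameters-previously-determined approximation, flagged in
reports — and each marker's effect is tested by Wald-F
(`alpha_hat^2 / var(alpha_hat)`) against F(1, n - 2); the denominator
degrees of freedom are a documented choice. Detection frequency counts
runs in which the tracked marker clears a Bonferroni 0.05 threshold by
default (`alphaPolicy` exposed, since the emulated study states none).

# Problem sizes and numerical choices

The package's study-scale runs use 371 lines and 2,000 markers (the full
9,926 is supported through `panelParams`); benchmark grids in the test
suite use 84-marker panels at the same 2.25 cM spacing, which preserves
the LD profile while keeping Random Forest runs short. Heritability and
QTL-share recovery average 20 phenotype seeds; generator calibration
averages 10 panels; detection frequency uses 100 scan runs with the
eigendecomposition of 2K computed once and reused.

Two desk-scale effects are worth knowing when reading benchmark output:

* **Reference-size monotonicity** is assessed as a positive trend
  (regression slope of cell accuracy on reference size, plus the largest
  reference beating the smallest). Cell means at 84 markers carry about
  one standard error of noise, and demanding a strictly non-decreasing
  chain across all four reference sizes would fail sporadically for the
  Random Forest even when the underlying trend is clearly positive.
* **Scan power at reduced marker counts** is structurally lower than at
  full scale: with few markers, each marker is a visible fraction of the
  kinship itself, so the polygenic correction absorbs part of the tested
  marker's own signal, and the per-marker background effects (variance
  split over ~2,000 rather than ~10,000 markers) add larger correlated
  noise to the causal marker's apparent effect. The power analysis in
  the acceptance material reports exactly what the scan computes under
  these conditions.

# Known limitations

Diploid/heterozygous phasing, MCMC haplotype sampling, pedigree-based
imputation and multi-trait prediction are out of scope. The HMM requires
fully observed reference lines per chromosome. The experiment driver
(`runExperiment`) caches completed accuracy cells by file name when an
output directory is given; it does not checksum artifacts.
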