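---
title: "Detecting correlated methylation units by image clustering"
author: "cmuscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting correlated methylation units by image clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmuscan)
```

## The problem

DNA methylation at nearby CpG dinucleotides is strongly correlated across
individuals, much as nearby SNPs form linkage-disequilibrium blocks. A
*correlated methylation unit* (CMU) is a run of four or more genomically
adjacent CpG probes whose methylation profiles are strongly inter-correlated
across samples. Two or more CMUs in the same genomic neighbourhood can
themselves be strongly (positively or negatively) correlated while being
separated by uncorrelated ("unsynced") probes; such groups form
*non-contiguous CMUs* and are candidates for long-range coordinated
regulation. `cmuscan` detects both kinds of unit from Illumina 450K/EPIC-style
beta-value matrices, compares CMU sets across tissues, calls
tissue-independent units, annotates them against regulatory and 3D-chromatin
features, and tests case-control differences in correlation structure.

## The image-clustering method (ICM)

Each chromosome is tiled into non-overlapping 250 kb windows anchored at
coordinate 0. Within a window, the Pearson correlation matrix of all probe
pairs is treated as an image whose pixels lie in [-1, 1], and passed through
four stages:

1. **Smoothing.** 2-D convolution with a normalized unequal-weight box
   kernel (symmetric border handling), then re-symmetrization and clipping.
2. **Thresholding.** Pixels with |r| below the cutoff `alpha` are set to 0;
   surviving pixels keep their sign, because strongly negative inter-probe
   correlation is unit-forming too.
3. **Edge detection.** On the support indicator of the thresholded image, a
   cut between adjacent probes is a boundary when *no* support crosses it
   within a near-diagonal band of two probe offsets — the image-gradient
   edges are exactly the places where correlation between (nearly) adjacent
   sites has fallen to zero. On an exact block-diagonal image this rule
   coincides with the positive-band-gradient formulation and with exhaustive
   maximal-interval search (both are tested); on noisy images the
   connectivity form is preferred because a single interior pixel that dips
   below the cutoff would otherwise split a genuine block in two.
4. **Unit calling.** Each inter-boundary run is accepted as a contiguous CMU
   when it has at least `min_cpgs` probes, at least `block_density` of its
   off-diagonal pixels survived the cutoff, and its mean |r| is at least
   `alpha`. The density-plus-mean rule operationalizes "overall strong
   correlation even when not every pair is high", which a hard pairwise
   threshold cannot express. Two called units separated by at least one
   unsynced probe are linked when the mean |r| over their inter-unit
   rectangle reaches `alpha`; connected components of the link graph with
   two or more members become non-contiguous CMUs, with per-pair signs taken
   from the signed rectangle means.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `window_size` | 250,000 bp | scan resolution; large enough for several units, small enough to keep matrices tractable |
| `alpha` | 0.6 | correlation cutoff; 0.4 is the cross-tissue preset, higher values reveal sub-units |
| `min_cpgs` | 4 | minimum adjacent probes per contiguous unit |
| `block_density` | 0.9 | minimum fraction of surviving off-diagonal pixels in an accepted block |
| `kernel` | center-weighted 3x3 | smoothing weights, see below |
| `band_width` | 2 | near-diagonal band used by edge detection |
| `min_overlap` | 30 | minimum complete sample pairs per correlation |
| `min_probes_per_window` | 4 (lenient) / 10 (stringent) | windows with fewer probes are skipped |

### Why the center-weighted kernel

The default kernel is `[[1,1,1],[1,24,1],[1,1,1]]/32`. The choice is driven
by a closed-form edge computation rather than taste: convolving an ideal
block of correlation *r* with a 3x3 kernel whose off-center weights sum to
`8w` multiplies the block's edge-row pixels by `1 - 3w` and its corner
pixels by `1 - 5w`. Rank-normalized estimates of a latent r = 0.8 block sit
near r = 0.75 at n = 200, so with the classical pyramid kernel
(`[[1,2,1],[2,4,2],[1,2,1]]/16`, edge factor 12/16) edge pixels land at
about 0.75 x 0.75 = 0.56–0.61 — squarely on the default cutoff — and the
block fails its own density rule roughly whenever sampling noise breaks the
tie. With `w = 1/32` the edge factor is 29/32 (edge pixels about 0.68) and
the corner factor 27/32 (about 0.63), so an ideal thresholded block is fully
dense and every pixel retains a comfortable noise margin, while smoothing
still averages the 8-neighbourhood enough to suppress isolated noise pixels
and to bridge single weak pairs near the diagonal. The pyramid kernel
remains available as `icm_kernel("pyramid")`, and any odd-sized matrix can
be supplied.

### Nesting of cutoffs

Because thresholding a fixed smoothed image at a higher `alpha` can only
shrink the support, boundary sets grow monotonically and probe runs refine:
units called at a higher cutoff are probe-contained in units called at a
lower cutoff on the same data (sub-CMUs). This is asserted end-to-end in the
test suite at `alpha` 0.4 / 0.6 / 0.8.

## Preprocessing

Probe distributions are converted to normal scores with the rank-based
inverse-normal transform `qnorm((rank - 3/8) / (n + 1/4))` (Blom offset for
all n; ties share average ranks; missing values stay missing and probes with
fewer than 3 observations are excluded). The Blom constant is used uniformly
rather than switching offsets with sample size: the difference is O(1/n) and
invisible after correlation, and a single formula keeps the transform
reproducible. For case-control work, transformed values are regressed on
covariates (OLS per probe on complete cases, categorical covariates
indicator-expanded) and the residuals carry forward, so correlations are
partial correlations. The order — transform, then residualize, then
correlate, each group separately — is a package decision where the
alternative (pooled residualization) is available via preprocessing both
groups together before splitting.

## Comparing CMU sets

The asymmetric similarity between CMU sets S1 and S2 is the fraction of S1's
units whose genomic region shares at least one basepair with some unit of S2
— a Tversky index with weights (1, 0). It deliberately distinguishes "S1 is
represented in S2" from the converse; the all-pairs matrix, its row/column
medians, and complete-linkage clustering on distance 1 - cor of its columns
summarize tissue relationships.

Tissue-independent (TI) regions stack one deduplicated dataset per tissue
(largest sample size wins, ties broken lexicographically) and keep maximal
basepair runs covered in *strictly more than* 80% of tissues — "more than
80%" is read as a strict inequality, so 8 of 10 tissues does not qualify.
Contiguous stacking first filters to units with more than 10 probes;
non-contiguous stacking uses spans (first basepair of the first member to
last of the last) of units with at least 3 members, tolerating member
boundary variation across tissues. No minimum TI region length is imposed
(1 bp suffices); imposing one is left to the caller's post-filter.

## Enrichment and chromatin context

Two complementary tests ask whether CMUs concentrate in a feature class:

* **Probe-based:** two-sided Fisher exact test on the 2x2 table of probe
  membership (in-CMU x in-feature) over all probes, plus an upper-tail
  hypergeometric variant. Exactness is verified against full enumeration of
  the hypergeometric support for every table with N <= 40.
* **Region-based:** the observed score counts distinct feature intervals hit
  by the CMU set; a matched background redraws, for each observed unit, a
  random region of identical length inside a uniformly chosen eligible
  window (>= 4 probes lenient, >= 10 stringent), 10,000 times by default.
  The background scores are modeled as a normal distribution and the
  upper-tail probability of the observed score is reported. A background
  region may fall in the observed unit's own window; excluding it would bias
  the null for dense windows. Type-I calibration under uniformly placed
  features is checked by a Kolmogorov-Smirnov test against Uniform(0,1)
  (the suite scales the background to 1,000 replicates x 200 null runs to
  keep runtime modest; the default remains 10,000).

Chromatin-context summaries report the fraction of probes in a feature, the
fraction of units hitting >= 1 interval, and among those the fraction
hitting exactly one; the A/B-compartment pair score is
`log(pct_cmu_overlap / pct_cpg_overlap)`, and TAD containment is the
fraction of spans crossing no TAD boundary. One shared basepair counts as an
intersection everywhere, matching the default of the interval tools these
analyses are usually run through.

## Differential correlation

Each group's scan defines its own units (contiguous units absorbed into
non-contiguous ones are collapsed out of the list); for every unit a paired
correlation matrix is built on the same probes in the other group, and two
tests must both pass after Bonferroni correction within the defining group's
family:

1. A chi-square comparison of the two matrices on Fisher-transformed
   off-diagonals: chi2 = sum over pairs of (z1 - z2)^2 / (1/(n1-3) +
   1/(n2-3)) with p(p-1)/2 degrees of freedom, testing that all off-diagonal
   differences are zero. The p = 2 case collapses to the classical
   two-sample Fisher-z test (asserted to 1e-10). Off-diagonals at |r| = 1
   are clipped to 0.9999 and flagged. The statistic treats pair-level z
   differences as independent; that is exact for p = 2 and calibrated under
   an independence null (rejection 3–8% at nominal 5% in the suite), while
   correlated nulls inflate its tails — which is precisely why the second
   test is required.
2. A one-sided unpaired Wilcoxon rank-sum test that the defining group's
   off-diagonal correlations are shifted right of the other group's by at
   least `mu` = 0.1 (a deliberately sensitive cut-off; raising `mu` proxies
   for smaller samples). The reference description mentions "diagonal
   entries", which are identically 1 in a correlation matrix; the package
   reads this as the off-diagonal entries, consistent with the matrix-test
   null. The reported effect size is the Hodges-Lehmann shift of
   (other - defining): negative values mean the defining group is the more
   correlated one.

Bonferroni families are per defining group and per test; "corrected for each
dataset separately" is ambiguous between cohort and group, and the
group-wise reading is the more conservative one under two scans.

## The synthetic-data generator

Validation runs on generated data with planted truth: probes are laid along
chromosomes with jittered gaps (mean 1,150 bp, array-like density), latent
signals are multivariate normal with the requested within-block and signed
inter-block correlations (non-positive-definite requests are repaired to the
nearest correlation matrix with a warning), and values are squashed through
the logistic function into (0,1). The squashing is monotone, so the
pipeline's rank-normal transform recovers the latent structure; a Beta
copula would add realism of marginal shapes but change nothing after
rank-normalization, which is why the simpler map was chosen. Case groups
attenuate mapped blocks' within-correlation; multi-tissue sets share one
layout with per-tissue block presence; a shared covariate effect can be
injected for residualization testing. Standard scenarios: `basic`
(n = 200, one 2.5 Mb chromosome, 20 blocks of 6–12 probes at within-r 0.8
among ~2,000 noise probes), `multitissue` (10 tissues, n = 100 each, 12-probe
blocks shared by 10/9/8/7/5/1 tissues), and `casecontrol` (n = 150 per
group, four 8-probe blocks, two attenuated 0.8 -> 0.4). What the generator
does *not* emulate — probe-type chemistry, batch effects, cell-type mixtures,
spatially decaying correlation, sex chromosomes — bounds what passing tests
can claim about real arrays: they demonstrate correctness of the algorithms
under the stated correlation model, not robustness to array artefacts.

## Numerical and degenerate-input choices

* Pairwise-complete correlation with an overlap floor of 30 pairs; pairs
  below the floor and zero-variance probes are set to r = 0 (flagged), so
  the image stage is total.
* Manifest positions are 1-based points; every emitted interval is BED
  0-based half-open; a unit's extent is [pos(first) - 1, pos(last)), so a
  single-probe interval has length 1.
* A probe exactly on a detected edge belongs to the left run; dataset
  dedup ties break lexicographically; all samplers take explicit seeds and
  run logs record them — identical configuration gives byte-identical
  BED/TSV outputs.
* Empty similarity denominators error (Asy with empty S1 is undefined);
  degenerate enrichment margins and zero-variance backgrounds are flagged
  rather than silently returning numbers.

## Scope and limitations

Windows are hard boundaries: units are never merged across windows, and a
diagnostic flag (`edge_flush`) marks units flush against a window edge that
may be truncations. The genome build is carried as metadata only. The suite
exercises problem sizes of roughly 1,000–2,200 probes per scan, 200 oracle
images, 1,000-replicate null calibrations and 50-replicate power runs —
sizes chosen so the full validation completes on a laptop-class single core
while keeping every Monte-Carlo bound comfortably away from its threshold.
Learning smoothing weights or thresholds from data is out of scope, as are
IDAT-level normalization, cell-type deconvolution and cross-build liftover.
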