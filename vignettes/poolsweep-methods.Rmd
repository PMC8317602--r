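---
title: "Scanning pool-seq data for selective sweeps: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning pool-seq data for selective sweeps: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsweep)
```

## The problem

Pooled whole-genome sequencing (pool-seq) estimates population allele
frequencies from read counts over a DNA mix of many individuals, without
genotyping any of them. When two closely related populations — here the
motivating case is a miniature dog breed recently derived from its parent
breed by artificial selection on body size — are each sequenced as pools,
regions that responded to selection leave three complementary signatures:

* locally elevated allele-frequency differentiation (F~ST~),
* locally depressed diversity in the selected population (pooled
  heterozygosity H~p~),
* an allele-frequency shift pattern decaying with recombination distance
  from the selected site (XP-CLR).

`poolsweep` computes all three over non-overlapping 25-kb windows,
intersects their top 1% tails into candidate sweep regions, and annotates
candidates with overlapping genes. Because raw pool-seq data of this kind is
large and external, the package ships a synthetic generator that emulates
the two-pool design with planted sweeps, so that the full pipeline is
testable and its operating characteristics measurable.

## Window statistics

**Weir–Cockerham F~ST~.** For one biallelic site with haploid sample sizes
$n_1, n_2$ and sample frequencies $\tilde p_1, \tilde p_2$,

$$MSP = \frac{n_1 n_2}{n_1+n_2}(\tilde p_1-\tilde p_2)^2, \qquad
  MSG = \frac{n_1\tilde p_1(1-\tilde p_1) + n_2\tilde p_2(1-\tilde p_2)}{n_1+n_2-2}, \qquad
  n_c = \frac{2 n_1 n_2}{n_1+n_2},$$

$$\hat F_{ST} = \frac{MSP-MSG}{MSP+(n_c-1)\,MSG}
             = 1-\frac{n_c\,MSG}{MSP+(n_c-1)\,MSG}.$$

Both algebraic forms are implemented and tested to agree at machine
precision, and the estimator is cross-checked against a literal two-level
ANOVA on 0/1 allele indicators. Windows aggregate sites by *ratio of sums*
(sum numerator and denominator separately) by default; *mean of ratios* is
available because pool-seq toolchains differ and the choice is worth
surfacing. No clamping at zero is applied — weakly differentiated windows
may be slightly negative, which is information, not error.

The haploid sizes default to $2\times$ the pool's diploid count (70 and 118
for the default 35/59 design). Pool-seq sample size is genuinely ambiguous
— reads resample a finite pool — so `n_mode = "min-depth"` caps $n_i$ at the
observed depth for users who prefer the conservative reading.

**Pooled heterozygosity.** With $n_{MAJ}, n_{MIN}$ the target pool's read
counts of the within-pool major/minor allele at each SNP,

$$H_p = \frac{2\,\sum n_{MAJ} \sum n_{MIN}}{(\sum n_{MAJ}+\sum n_{MIN})^2}
  \in [0, 0.5],$$

summed over the window's SNPs, and $-ZH_p = (\mu_{H_p}-H_p)/\sigma_{H_p}$
with moments taken over all retained windows. The standard deviation uses
the population (divide-by-$N$) convention so the standardization identities
(mean 0, sd 1) hold exactly; at tens of thousands of windows the difference
from the sample convention is negligible. The Z-parameters are estimated
*after* discarding windows with fewer than 10 SNPs, i.e. over the same set
of windows that the percentile selection sees.

**XP-CLR.** The null model says the object population's latent frequency
$p$ drifted around the reference sample frequency $\tilde p_1$ as a
Gaussian with variance $\omega\,\tilde p_1(1-\tilde p_1)$, truncated to
$[0,1]$ with the clipped tails as boundary point masses. The sweep model
transforms that density through star-like hitchhiking: a lineage at
recombination distance $r d$ from a sweeping allele escapes with
probability $c = 1-(2Ns)^{-rd/s}$, and conditional on pre-sweep frequency
$x$ the currently counted allele was the hitchhiker with probability $x$,
giving post-sweep frequency $(1-c)+cx$ (else $cx$). Observed pool counts
enter through a binomial emission in read depth — the pool-seq analogue of
genotype-based formulations, and deliberately so, since no genotypes exist.
The per-site likelihood integrates emission over density by Gauss–Legendre
quadrature; the window score is
$2\,\max_s \sum_i [\ell_i(s) - \ell_i(0)]$ over a grid of 0 plus ten
log-spaced coefficients in $[10^{-4}, 0.1]$, with distances measured from
the window center. Scores are therefore non-negative, zero exactly when the
null wins everywhere, and Z-normalized across retained windows.

Numerical choices that matter:

* *Quadrature.* Gauss–Legendre nodes cluster at the frequency boundaries,
  where the drift density is narrowest; 256 points (default) agree with a
  10$\times$ finer integration to better than $10^{-6}$ in log likelihood,
  which the acceptance tests assert. The independent reference in the unit
  tests is a separately written 4096-point midpoint integrator.
* *Floors.* The drift standard deviation is floored at 0.01 so the density
  never collapses below the quadrature's resolving power, and likelihoods
  are floored at $10^{-300}$ before the log.
* *Drift variance $\omega$.* Estimated by the moment ratio
  $\mathrm{mean}[(\tilde p_2-\tilde p_1)^2/(\tilde p_1(1-\tilde p_1))]$
  with $\tilde p_1$ clamped away from 0/1 by half a quadrature step. Sites
  monomorphic in the reference *sample* are excluded first: they carry no
  drift information, and at 30× depth the clamped denominator would
  otherwise inflate $\omega$ several-fold and flatten every score to zero.
  Because read-sampled frequencies enter on both sides, $\omega$ absorbs
  pool- and read-sampling noise on top of true drift; that makes the null
  slightly generous and the scan slightly conservative, which we accept:
  normalization and percentile selection operate on relative scores.
* *Degenerate normalization.* On a fully neutral genome every window can
  legitimately prefer the null, making all raw scores zero. `window_xpclr`
  then reports all-zero normalized scores with a warning instead of
  erroring, and the percentile selection falls back to its deterministic
  (chromosome, start) tie-break — the three-way intersection stays
  essentially empty, which is the correct behavior on data without sweeps.

**Selection and intersection.** `top_quantile` selects exactly
$\lceil qN\rceil$ windows (869 of 86,886 at $q=0.01$), reports the least
extreme selected value as the threshold, and breaks ties by coordinate.
Candidates are the exact three-way intersection; adjacent candidate windows
are reported as separate rows (a gene spanning both appears in each), and a
gene overlaps a window iff it covers at least 1 bp of the window's
half-open occupancy — a gene ending exactly at the window start does not
count.

## The synthetic generator

The generator is the package's stand-in for the study design it emulates:
two populations split from a common ancestor, pooled at 35 vs 59 diploids,
sequenced at ~30× with base error, plus indels to exercise the
proximity filter. It is deliberately minimal:

* Ancestral frequencies are uniform on $[0.05, 0.95]$, so the MAF filter
  operates in its realistic regime rather than on a wall of rare alleles.
* Each population's frequency is an independent Balding–Nichols draw,
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, giving
  $\mathrm{Var} = F\,p(1-p)$. The default $F = 0.05$ puts genome-wide
  F~ST~ near the weak differentiation typical of recently diverged breed
  pairs. A useful calibration subtlety, asserted in tests: the moment ratio
  that estimates $\omega$ has expectation well above the naive
  $2F/(1-F)$ because the reference frequency sits in the denominator; the
  tests freeze the expected value from an independent Monte-Carlo oracle
  rather than a back-of-envelope constant.
* Sweeps use the same star-like hitchhiking approximation the XP-CLR model
  assumes, with the hitchhiking allele drawn per site with probability
  equal to its frequency — generator and model are the same physics, which
  is what makes the recovery experiment a test of the machinery rather
  than of model mismatch. Defaults $s = 0.05$, $N = 10^4$,
  $r = 10^{-8}$/bp give a footprint half-width (escape probability 0.5) of
  about 0.5 Mb.
* Sequencing is pool-binomial then depth-binomial: pool frequency
  $\sim \mathrm{Bin}(2\,\text{individuals}, p)/2\,\text{individuals}$,
  depth $\sim$ Poisson(30) truncated at $\ge 1$ (zero-depth records never
  reach a variant caller), alternate reads binomial at the error-perturbed
  pool frequency. Transitions are drawn with probability 0.65, giving an
  expected Ts/Tv near 1.86, the value typical of dog variant sets.
* Indels are Poisson-scattered at $10^{-3}$/bp (the genome-wide density
  implied by ~2.3M indels in a 2.4-Gb genome).

What the generator does *not* emulate: linkage disequilibrium beyond the
deterministic hitchhiking transform (sites are exchangeable given the
sweep), mapping artifacts, reference bias, variable recombination, or
demographic history beyond a single clean split. Passing the recovery tests
therefore shows the machinery detects the modeled signal at the stated
design — it does not certify power on real genomes, where LD, repeat
content and uneven coverage all intrude.

## SNP filters

The filter rules are the standard pool-seq quality gate: discard SNPs with
combined minor allele frequency $< 0.05$ (counts summed over both pools —
the variant set is joint), any pool's depth $< 10$ (per-pool by default,
combined by flag), quality $< 20$, or within 15 bp of an indel
(inclusive: distance 15 is discarded, 16 retained — the boundary is
unit-tested so the reading is explicit). Indel records are dropped from the
SNP output but retained as exclusion anchors. Records from sync input carry
no quality and pass the quality rule. Filtering is idempotent and the
report's accounting (retained + uniquely discarded = input) is
property-tested.

## Problem sizes and determinism

The validation experiments run at the emulated study's design: a 20-Mb
four-chromosome genome at SNP density $3\times10^{-3}$/bp (~60k SNPs,
800 windows), three planted sweeps at $s = 0.05$, 20 seeded replicates for
recovery and 11 for the neutral control. One replicate takes a few seconds;
the whole suite some minutes. Every random stage flows from a single seed
(`sim_config(seed = )` or the acceptance script's `--seed`), and rerunning
the pipeline with an identical configuration reproduces the statistic files
checksum-for-checksum.

## Known limitations

* Two pools only; the multi-population Weir–Cockerham generalization is out
  of scope.
* The XP-CLR implementation follows the published model but is not a
  numerical clone of any external tool; scores should be compared within a
  run (percentiles), not across tools.
* Whether score normalization should be genome-wide or per chromosome is
  not settled usage; genome-wide is the default here.
* The published candidate table bundled for consistency checks prints
  H~p~/−ZH~p~ to three decimals, which bounds how tightly the affine
  relation can be recovered (residuals up to ~0.013 from rounding alone).
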