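---
title: "Methods: diversity-load optimization and evolvability monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity-load optimization and evolvability monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedopt)
```

`seedopt` supports seed-sourcing decisions for regional admixture
provenancing: given SNP genotypes for individuals from candidate source
populations and a functional annotation of the SNPs, it scores every
n-population combination by pooled genetic diversity relative to genetic
load, and, once seedlings are in the ground, quantifies how much
quantitative-trait evolvability pooling bought. This vignette documents
the models, the tunable parameters, the numerical conventions, and what
the synthetic-data generator does and does not emulate.

## Diversity and load for a pool of individuals

All scoring starts from pooled alternate-allele frequencies. For a pool
(one population or the union of several), each SNP's frequency is

> p = (sum of dosages over called individuals) / (2 × number of called
> individuals),

with missing genotypes excluded from the denominator per SNP and no
imputation — the simplest unbiased frequency estimate. A SNP with no
called alleles in a pool is dropped from that pool's metrics.

**Genetic diversity** is mean expected heterozygosity,
`GD = mean(2 p (1 - p))` over all usable SNPs. Two conventions are worth
making explicit:

- SNPs monomorphic *in the pool* stay in the mean (contributing 0), so
  GD is a per-genotyped-site average over the fixed SNP panel and is
  comparable across pools of the same panel. The alternative —
  averaging only over polymorphic-in-pool sites — changes GD's scale
  pool by pool and would make the combinatorial ranking depend on how
  many sites happen to segregate in each subset.
- No small-sample correction (no 2n/(2n−1) factor) is applied; GD is
  the plain plug-in estimator, and all pools compared in one ranking
  carry comparable sample sizes.

**Genetic load** uses the functional annotation: with `Pn` and `Ps` the
counts of nonsynonymous and synonymous SNPs *segregating* in the pool
(0 < p < 1) and `fn`, `fs` their mean alternate-allele frequencies,

> GL = (Pn · fn) / (Ps · fs),

which is identically the ratio of summed alternate-allele frequencies of
the two classes. Sites fixed for the alternate allele are not
segregating and are excluded from both counts. The effect labels treated
as nonsynonymous are the amino-acid-changing SnpEff categories
(missense, splice acceptor/donor/region, start lost, stop gained/lost);
`synonymous_variant` is the silent class; everything else — including
unannotated SNPs — is ignored by GL. When several labels annotate one
SNP, the worst consequence wins (nonsynonymous > synonymous > other),
a deterministic precedence chosen over any attempt to weight compound
annotations. Frequencies are alternate-allele (non-reference)
frequencies throughout; no ancestral polarization is attempted, so GL is
a relative drift-load proxy rather than an absolute deleterious-allele
count, and it is only meaningful compared across pools annotated against
the same reference.

A pool with no segregating synonymous SNPs has undefined load; the
package raises an explicit error rather than returning NaN, since any
realistic exome panel has thousands of synonymous sites.

## Optimizing source combinations

Candidate sets are enumerated exhaustively: all `C(k, n)` subsets of the
k candidate populations, emitted in lexicographic order. Exhaustive
search is deliberate — the largest realistic instance (23 candidates,
sets of 5) is 33,649 pooled scorings, well inside desk scale — and a cap
(default 10^6 sets) guards against accidental blow-ups. Scoring pools
the member populations' individuals via per-population sufficient
statistics (summed dosages and called-allele counts per SNP), so each
set costs two vector additions rather than a pass over raw genotypes;
tests verify this path against a naive per-set recomputation.

Sets are ranked by GD:GL descending, ties broken lexicographically on
the sorted population IDs so output is deterministic. The percentile of
a chosen set is count-based:

> percentile = 100 × (#sets with ratio ≤ chosen ratio) / #sets,

chosen so that a unique best set sits at exactly the 100th percentile,
matching how practitioners read "the best combination". Interpolated
percentile definitions would report 100(1 − 1/n)-type values for the
argmax and were rejected. Qualitative vetting of sets (site access, cone
crop, expert opinion) is represented as include/exclude population lists
in the run configuration, not modeled.

## Evolvability from monitoring data

Seedling height is the monitored trait. For each source within a site,
heights of surviving seedlings are first passed through a Tukey
interquartile-range filter: values outside `[Q1 − m·IQR, Q3 + m·IQR]`
are removed, with quartiles computed by the linear-interpolation
convention (`quantile(type = 7)`, R's default) and `m = 1.5` (the
classic fence multiplier; configurable). The filter is single-pass and
deliberately not idempotent — re-filtering filtered data can remove
more as the fences shrink.

Filtering uses the observed plot heights. Mixed-model smoothing of the
height data (site/plot random effects) before filtering is a reasonable
alternative that this package does not implement; with plots randomized
within sites the observed and modeled heights differ mainly by shrinkage,
which narrows fences slightly.

With no pedigree in a restoration planting, the genetic variance is
approximated by scaling the phenotypic variance with an external
broad-sense heritability estimate:

> V_G = H² · V_P,  CV_G = √V_G / X̄,

with `V_P` the sample variance (denominator n − 1) and X̄ the trait
mean. The default `H² = 0.3962` is a common-garden estimate for
one-year red-spruce seedling height; users working on other systems
must supply their own. CV_G is scale-free (doubling all heights leaves
it unchanged), which is what makes single-source and pooled values
comparable.

The pooled estimate is computed on the union of the per-source filtered
heights, then put on the same sample-size footing as single sources by
bootstrap: 1000 replicates each resampling N = 200 heights with
replacement, with the replicate mean and SD reported as the pooled CV_G
and its uncertainty. Because the pooled CV_G is a bootstrap mean over
subsamples rather than a plug-in value, it is a stochastic quantity: it
need not equal √(H²·V_P_pooled)/X̄ computed from the pooled moments, and
with divergent source means it is typically larger. The fold gain
reported is pooled CV_G over the *minimum* positive single-source CV_G
("up to X× higher"), rounded to one decimal.

Survivorship is purely descriptive here: per plot, the proportion of
alive plants out of the number initially planted (default 40), averaged
over plots per source within site. Significance testing of source
effects on survival or height (binomial/Gaussian mixed models) is
routine and out of scope.

## The synthetic-data generator

The generator exists so the whole pipeline is testable — and its
calibration checkable against closed-form expectations — without any
genotype download.

**Genotypes.** Each locus draws an ancestral alternate-allele frequency
p̄ ~ Beta(a, b) (defaults a = 0.4, b = 1.6: a rare-skewed exome-like
spectrum). Each population i then draws
p ~ Beta(p̄(1−F_i)/F_i, (1−p̄)(1−F_i)/F_i) — the Balding–Nichols model,
in which F_i plays the role of that population's drift (Fst) since the
regional split. Balding–Nichols was chosen over other exchangeable-Fst
models because its conditional moments are closed-form,
E[2p(1−p) | p̄] = 2p̄(1−p̄)(1−F), which gives the tests an independent
numeric-integration oracle for the simulated heterozygosity (including
the binomial finite-sample factor 1 − 1/(2n) of the plug-in estimator).
Genotypes are Binomial(2, p) dosages with uniform missingness (default
5%).

Load differentiation is induced mechanically rather than by simulating
selection: nonsynonymous loci have their population frequency replaced
by `min(λ_i · p, 0.5)`. GL as defined responds only to class-wise
frequencies, so frequency inflation is the minimal mechanism that makes
populations differ in load; the 0.5 cap keeps deleterious variants at
intermediate frequency, mimicking drift load rather than fixation. The
defaults (k = 23 populations of 6 individuals, 2000 nonsynonymous +
2000 synonymous + 1000 other loci, F spanning 0.05–0.25, λ spanning
1–1.5) produce panels whose GD (~0.2), GL (~0.9) and GD:GL saturation
with set size sit in the regime observed for range-edge conifer exome
panels, while keeping the full C(23,4) scoring under half a minute on
one CPU.

**Field trials.** Seedlings are planted in single-source plots
(default 5 plots × 40 seedlings per source and site, the monitoring
design's density). Each seedling survives with its source's survival
probability (defaults spanning 0.75–0.95) and, if alive, has height
μ_s + g + e with g ~ N(0, V_G), e ~ N(0, V_E) and
V_G = H²/(1−H²) · V_E so the within-source genetic fraction of variance
equals the target H² (default 0.3962; default source means 25–28 cm).
The latent g and e are returned as an attribute so calibration tests can
check realized V_G/V_P without re-deriving it from the phenotype.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: linkage between loci (all loci are
exchangeable and independent), genotype-likelihood uncertainty from
low-coverage sequencing (the package consumes hard genotypes; likelihood
handling is upstream preprocessing), non-equilibrium demography beyond
single-parameter drift, selection, plot-level environmental effects
(plots within a site share one residual distribution), and
genotype-by-site interaction. Conclusions about method behavior on real
panels rest on the arithmetic identities and invariance properties, not
on the simulator's realism.

## Numerical conventions and degenerate inputs

- Quartiles: `quantile(type = 7)` (linear interpolation) everywhere.
- Variances: denominator n − 1 throughout, including inside bootstrap
  replicates; replicate variances are clamped at zero against
  floating-point cancellation on near-constant resamples.
- Ties in ranking: lexicographic on sorted population IDs;
  reproducibility is worth more than any statistical tie-break.
- All stochastic stages (simulators, bootstrap) take a seed and restore
  the caller's RNG state afterwards; the pipeline derives per-site
  bootstrap seeds from the run seed, so a config plus seed reproduces
  every output byte.
- Degenerate inputs fail loudly: empty pools, pools with no usable
  SNPs, GL with no segregating synonymous sites, bootstrap with N < 2,
  set sizes exceeding the candidate count, and chosen sets that were
  never scored all raise informative errors rather than propagating
  NaN.

## Problem sizes used in the test suite

The suite favors small, fast instances with closed-form or brute-force
oracles: hand-transcribed fixtures of a few SNPs, random panels of up to
8 populations for ranking equivalence, 10^4-locus single-statistic
simulations for the Balding–Nichols and load-ordering calibrations, 800
seedlings for H² recovery, and one full 23-population panel for the
C(23,4) = 8855 enumeration. Bootstrap consistency is checked at
B ∈ {100, 400, 1600} with 25–30 outer replicates, enough to resolve the
expected 4× noise reduction without Monte-Carlo flakiness.
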