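# seedopt

Genomics-assisted seed source selection for ecological restoration.

When restoring a fragmented forest, which natural populations should seed
be collected from? Sourcing from a single local stand risks importing low
diversity and drift load; pooling several sources within a region
("regional admixture provenancing") can raise the genetic diversity of the
restored population while keeping its regional identity. `seedopt`
implements the quantitative side of that decision for restoration
geneticists and practitioners working from a SNP panel of candidate
populations and, after planting, from seedling monitoring data.

## The metrics

For any pool of individuals (one population or a pooled set):

- **Genetic diversity** `GD` is the mean expected heterozygosity across
  the SNP panel, `GD = mean over SNPs of 2p(1-p)`, with `p` the pooled
  alternate-allele frequency (missing genotypes excluded per SNP from the
  denominator).
- **Genetic load** `GL` is a drift-load proxy from functional annotation:
  `GL = (Pn * fn) / (Ps * fs)`, where `Pn`, `Ps` count the nonsynonymous
  and synonymous SNPs segregating in the pool and `fn`, `fs` are their
  mean alternate-allele frequencies.
- **GD:GL** is the selection score: diversity per unit deleterious burden.
  All `C(k, n)` n-population sets from k candidates are scored
  exhaustively and ranked; a chosen set is placed on the distribution by
  its count-based percentile (`100 x #sets with ratio <= chosen / #sets`).
- **Evolvability** of a seedling trait is the genetic coefficient of
  variation `CV_G = sqrt(V_G) / mean`, with `V_G = H^2 * V_P` scaled from
  the phenotypic variance by an external broad-sense heritability
  estimate (default 0.3962 for one-year seedling height). Pooled-source
  `CV_G` is bootstrapped (1000 replicates of N = 200 individuals, sampled
  with replacement) so it is comparable with single-source estimates.

A Balding–Nichols genotype simulator (per-population drift around
ancestral Beta frequencies, plus a nonsynonymous frequency-inflation knob
that differentiates populations in load) and a plot-structured field-trial
simulator make every stage testable without any external data.

## Worked example

```r
library(seedopt)

# a small synthetic candidate panel: VCF + annotation + population map + traits
paths <- write_fixture("demo", preset = "tiny", seed = 11)
g   <- read_genotypes(paths[["vcf"]], paths[["pop_map"]])
ann <- read_annotation(paths[["annotation"]])

# score every 2-population source set and rank by GD:GL
ranked <- rank_sets(score_sets(g, ann, enumerate_sets(population_ids(g), 2)))
ranked[, c("set_id", "gd", "gl", "ratio", "rank", "percentile")]
#>    set_id    gd   gl  ratio rank percentile
#> 1 P03+P04 0.176 1.02 0.1718    1      100.0
#> 2 P01+P04 0.180 1.13 0.1585    2       83.3
#> 3 P02+P04 0.196 1.53 0.1284    3       66.7
#> 4 P01+P03 0.152 1.42 0.1070    4       50.0
#> 5 P02+P03 0.163 1.93 0.0847    5       33.3
#> 6 P01+P02 0.168 2.04 0.0821    6       16.7

# evolvability of seedling height, single sources vs the pooled stand
tr  <- read_traits(paths[["traits"]])
tab <- evolvability_table(tr, h2 = 0.3962, seed = 11)
tab
#>   site source xbar   v_p   v_g   cv_g boot_sd n_used n_removed
#> 1   S1    P01 27.9 1.095 0.434 0.0236      NA     18         0
#> 2   S1    P02 26.2 0.434 0.172 0.0158      NA     14         3
#> 3   S1    P03 25.5 1.002 0.397 0.0247      NA     13         1
#> 4   S1 pooled 26.7 1.936 0.767 0.0324 0.00138     45         0

fold_gain(tab$cv_g[tab$source == "pooled"], tab$cv_g[tab$source != "pooled"])
#> [1] 2.1
```

The top line reads: pooling populations P03 and P04 gives pooled expected
heterozygosity 0.176 at load 1.02, the best diversity-per-load of the six
candidate pairs (100th percentile). The evolvability table shows the
pooled stand's `CV_G` (0.032, bootstrap SD 0.0014) exceeding every single
source — here 2.1x the weakest source — because divergent source means
widen the pooled phenotypic variance.

`run_pipeline(config, out_dir)` executes the whole chain
(score → optimize → evolvability → survivorship) from a YAML config and
writes ranked-set, evolvability and survivorship TSVs plus a JSON report;
`inst/scripts/seedopt.R` wraps the same functions as shell subcommands
(`simulate`, `score`, `optimize`, `evolvability`, `report`).

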