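# coexNeighbors

Chromosomal neighbours tend to be co-expressed in every eukaryote examined,
but several mechanisms can produce that signal: a shared chromatin
environment that opens or closes over both genes, bi-directional
transcription from a single shared promoter, and transcriptional
interference when one gene's polymerase runs past its poly(A) site into a
close downstream neighbour. `coexNeighbors` implements a pipeline for
teasing these apart in compact genomes (built around the *Arabidopsis
thaliana* setting of many sub-kilobase intergenic distances), for anyone
analysing neighbouring-gene co-expression from a genome annotation plus a
log2 expression matrix.

## What it computes

Given gene pairs that are direct chromosomal neighbours (no intervening
annotated gene, neither member overlapping another gene), classified by
orientation —

- **bi-directional (divergent, ←→)**: 5' ends face the intergenic region,
- **uni-directional (→→ / ←←)**: same strand,
- **convergent (→←)**: 3' ends face the intergenic region,

— the package computes each pair's co-expression *r* (Pearson correlation
of the two genes' log2 expression vectors across experiments), profiles it
by the number of intervening genes and by intergenic distance (100 bp bins),
and contrasts orientation-by-distance group means (split at 400 bp) against
a background of 100,000 random gene pairs using Wilcoxon rank-sum tests.

The decomposition then separates three components. With `m_bd>`, `m_cv>`
the long-distance (> 400 bp) bi-directional and convergent means, `m_bd<`,
`m_cv<` the close (< 400 bp) means, and `r0` the random-pair mean:

```
chromatin effect        c   = (m_bd> + m_cv>)/2 - r0
promoter fraction       p   = (m_bd< - c) / m_bd<
interference fraction   f   = (c - m_cv<) / c
```

Long-range divergent and convergent pairs can share neither promoters nor
3' ends, so their distance-independent excess over random pairs estimates
the chromatin effect; uni-directional pairs are excluded from `c` because
read-through can couple them even at long range. A baseline-consistent
interference variant using `m_cv< - r0` is reported alongside `f`.

Because a full-scale reference dataset (a TAIR genome annotation plus
over a thousand ATH1 hybridizations) is not shipped, the package includes
a latent-factor simulator
(`simulateFixture`) whose ground truth is exactly the three mechanisms with
known strengths `a` (chromatin), `b` (promoter), `delta` (interference),
plus closed-form expected pair correlations — so the entire pipeline is
validated by parameter recovery.

## Worked example

```r
library(coexNeighbors)

cfg <- simConfig(nChrom = 2, genesPerChrom = 500, nExperiments = 300,
                 seed = 42)                   # a=0.04, b=0.11, delta=0.4
fx  <- simulateFixture(cfg)
report <- analyzeNeighbors(fx$annotation, fx$matrix,
                           nRandom = 20000, maxIntervening = 2, seed = 42)
report$table2[, c("group_label", "mean_r", "sem_r", "n", "p_vs_random")]
#>            group_label mean_r   sem_r   n p_vs_random
#> 1  bidirectional_short 0.1515 0.00512 122    2.70e-71
#> 2 unidirectional_short 0.0257 0.00362 256    7.99e-12
#> 3     convergent_short 0.0271 0.00530 126    1.70e-07
#> 4   bidirectional_long 0.0413 0.00507 130    2.73e-13
#> 5  unidirectional_long 0.0370 0.00381 237    1.13e-19
#> 6      convergent_long 0.0532 0.00517 127    1.85e-20
```

Close bi-directional pairs stand out (0.15 ≈ a + b), close convergent and
uni-directional pairs are suppressed (≈ a(1 − delta) = 0.024), and the
long-distance groups sit near the chromatin level a = 0.04. The
decomposition recovers the generating parameters:

```r
report$decomposition[c("chromatin_effect", "promoter_fraction",
                       "interference_fraction")]
#> $chromatin_effect       0.0470
#> $promoter_fraction      0.690      # truth b/(a+b) = 0.733
#> $interference_fraction  0.424      # truth delta   = 0.40
```

Desk arithmetic on published group means works standalone:

```r
decomposeMeans(0.060, 0.050, 0.014, 0.152, 0.024, rounding = "printed")
#> DecompositionResult (rounding: printed )
#>   chromatin effect:      0.0400
#>   promoter fraction:     0.7333
#>   interference fraction: 0.4000 (baseline-consistent: 0.7500)
```

`readGFF3()` / `readExpressionMatrix()` load real annotations and matrices;
`filterTandemDuplicates()` (E-value < 0.2 on a supplied pairwise-similarity
table) and `excludeGeneList()` apply the optional duplicate/bicistronic
filters; `writeReport()` serialises the full report to JSON.

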