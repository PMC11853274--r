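# spliceDispersion

Positional dispersion analysis of hexamer subsets around human acceptor
splice sites.

## What it does, and for whom

The 3' (acceptor) end of an intron sits in a structured sequence
neighbourhood: a pyrimidine-rich tract and branch point upstream, the
invariant AG at positions −2/−1, exonic sequence downstream. Much of this
structure lives not in single-base composition but in correlations between
nearby bases. This package is for sequence analysts who want to read that
correlation structure out of aligned splice-site windows — and to test
whether it differs between classes of splice sites — without staring at
4096 hexamer frequencies per position.

The core statistic: partition the 4^6 = 4096 hexamers, for each
dinucleotide XY, into the **XY1** subset (hexamers containing XY as a
contiguous substring; 1185 words for X ≠ Y, 991 for X = Y) and the
complement **XY0** (2911 / 3105). At each aligned site *s*, with hexamer
counts across *N* windows, compute the dispersion

ρ_XY(s) = σ_XY(s) / σ(s),

the ratio of the population standard deviation of the subset's counts to
that of all 4096 counts. ρ < 1 flags conservative (narrower than
background) usage of XY-containing hexamers — stronger base correlation —
and ρ > 1 more random usage. Windows are 100 bases, labelled −50..−1 and
+1..+50 (no 0), giving 95 hexamer start sites −50..+45.

Around this the package provides:

* **Splice catalogue** — introns from a GTF, the bipartite donor–acceptor
  graph, acceptor modes (common / constitutive / alternative, plus
  normal / exonic / intronic sub-modes for alternative acceptors) and the
  100-bp exclusion filters.
* **Window extraction** — aligned, strand-aware 100-base windows from a
  genome FASTA.
* **Dispersion profiles** — per-site ρ for all 16 patterns and both
  subset classes.
* **Region statistics** — paired t-tests across sites between modes,
  per-region (upstream −50..−7, core −6..+1, downstream +2..+45; df
  43/6/43), Benjamini–Hochberg FDR within each region's family, star
  annotation, and a three-way significance grouping per pattern.
* **Synthetic generator** — seeded acceptor-like windows with
  configurable composition and dinucleotide injections, plus a planted
  toy genome/annotation, so the whole pipeline runs and is tested with no
  external downloads.

## Worked example

Three synthetic modes, 1000 windows each, with a 3× AG enrichment planted
in the alternative mode over labels +5..+30:

```r
library(spliceDispersion)

part <- kmerPartition(6)
part
#> KmerPartition: k = 6 ( 4096 k-mers ), 16 dinucleotide subsets
#>   XY1 sizes: 1185 (X != Y) / 991 (X = Y)
subsetSizes(part)[c("AG", "AA"), ]
#>     XY1  XY0
#> AG 1185 2911
#> AA  991 3105

cfg <- generatorConfig(nPerMode = 1000, seed = 1,
  injections = data.frame(pattern = "AG", from = 5, to = 30,
                          multiplier = 3, mode = "alternative"))
res <- runSyntheticMode(cfg, tempfile())

subset(res$tests, pattern == "AG" & region == "downstream")[, -1]
#>         region       mode_a       mode_b         t df        p_raw        p_adj stars group
#> 103 downstream       common constitutive -2.228900 43 3.109862e-02 4.664793e-02     *     A
#> 104 downstream       common  alternative -9.775541 43 1.711563e-12 8.215503e-11  ****     A
#> 105 downstream constitutive  alternative -9.052367 43 1.619712e-11 2.591540e-10  ****     A
```

The injected mode separates from both others at adjusted p ≈ 1e-10 in the
downstream region (the common–constitutive pair, drawn from the identical
generator, sits at the significance boundary — the paired t across
autocorrelated sites is mildly anticonservative, which is why null
behaviour is checked as a smoke bound, not an exact 5% calibration). The
grouping table mirrors this: in the downstream region AG leaves group C
(no significant pairs), while the un-injected core region stays entirely
in group C:

```r
g <- significanceGroups(res$tests)
table(g$region, g$group)
#>               A  B  C
#>   core        0  0 16
#>   downstream  6  8  2
#>   upstream    0  9  7
```

(Patterns overlapping AG-rich hexamers — GA, CA, TG, … — shift with the
injection too; an enrichment of AG necessarily perturbs the counts of
hexamers shared with other subsets.)

The annotation path runs from files instead:

```r
paths <- writeToyAnnotation("toy")      # planted genome + GTF + truth
res <- runAnnotationMode(paths$genome, paths$gtf, "toy/out")
table(res$acceptors$mode)
#> alternative       common constitutive
#>           5            4            1
```

A thin command-line front-end over the same functions is installed at
`inst/scripts/splice-dispersion.R` (subcommands `run`, `simulate`,
`catalog`, `partition`).

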