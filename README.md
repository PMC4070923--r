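# mitoComp

Comparative analysis of circular insect mitochondrial genomes in R.

Insect mitogenomes are ~16 kb closed circles carrying 13 protein-coding
genes (PCGs), 22 tRNAs, two rRNAs and a long non-coding control region
(CR). Comparative studies of these genomes keep answering the same set of
questions: how tightly are genes packed (overlaps and intergenic spacers on
the circle), how strongly is the composition biased toward A+T, how is that
bias distributed over synonymous and non-synonymous codon positions, how
fast does each gene evolve at each class of site, and what conserved motifs
does the control region carry. `mitoComp` implements that whole workflow as
composable, tested functions, for molecular evolution researchers working
on mitogenome papers and for anyone needing degenerate-site statistics on
codon-aligned ortholog sets.

## What it computes

**Circular annotation arithmetic.** Features live on a 1-based inclusive
circle (strand `J` = majority, `N` = minority; origin-wrapping features
supported). For adjacent features *f*, *g* the signed gap is
`start(g) − end(f) − 1`: positive gaps are intergenic spacers, negative
gaps gene overlaps. On a fully annotated circle,
`sum(feature lengths) + sum(signed gaps) = genome length` — an invariant
the package checks for you.

**Composition and codon usage.** Base composition by region, strand and
codon position; relative synonymous codon usage

> RSCU(c) = n(c) · |family| / Σ<sub>c′ ∈ family</sub> n(c′),

with families defined by a genetic code (default: NCBI translation
table 5, invertebrate mitochondrial); and the ratio of G+C-rich
(Pro, Ala, Arg, Gly) to A+T-rich (Phe, Ile, Met, Tyr, Asn, Lys) codons.

**Degenerate-site classes.** Every codon position is 0-, 2- or 4-fold
degenerate according to how many of the four nucleotides preserve the
amino acid (3-fold positions are binned with 2-fold). Across a
codon-aligned ortholog set, a site keeps a class only when all species
agree on its fold (configurable to reference-species assignment); per
class the package reports A+T content as mean ± SD over species.

**Divergence.** Per class, the nucleotide substitution frequency is the
mean over species pairs of the Jukes–Cantor corrected p-distance
`d = −(3/4) ln(1 − 4p/3)` restricted to the class's sites (pairs at
p ≥ 0.75 are saturated and excluded with a warning). Substitution-count
ratios `R_class = substitutions at class / substitutions at all classes`
use raw counts and sum to 1. Protein divergence is the Poisson-corrected
amino-acid distance `d = −ln(1 − p)`, averaged over all pairs (ASD).

**Correlation battery.** Pearson r with the classical two-tailed t-test
over any named column pairs of the per-gene statistics table.

**Control-region scanning.** Poly-T stretches (both strands), [TA(A)]n
stretches downstream of a poly-T, purine-rich blocks, exact tandem repeats
(maximally extended, fractional trailing copies), ungapped spacer→CR
counterpart search on both strands, and perfect stem-loop (hairpin)
detection — all pure functions reporting 1-based J-strand coordinates,
with BED-like TSV export.

**Synthetic data.** A simulator plants overlaps/spacers and CR motifs at
recorded coordinates, and evolves codon-aligned ortholog sets on a star
phylogeny with independent per-class substitution rates and per-class
A+T bias, so every stage of the pipeline is testable against known ground
truth without downloading anything.

## Worked example

```r
library(mitoComp)

# boundary accounting for an annotated 16 kb mitogenome
tsv <- system.file("extdata", "bminax_gene_table.tsv", package = "mitoComp")
gt  <- readGeneTable(tsv, genomeLength = 16043)
computeBoundaries(gt)
#> BoundaryReport over 38 adjacent pairs
#>   overlaps: 43 bp in 12 segments (1-17 bp)
#>   spacers:  178 bp in 16 spacers (2-42 bp)
```

So this genome's genes overlap by 43 bp at 12 boundaries and are separated
by 178 bp of intergenic spacer in 16 places — the tight packing typical of
insect mitogenomes.

```r
# correlations over the bundled per-gene class statistics (13 PCGs,
# summarised over ten tephritid fruit-fly species)
stats <- system.file("extdata", "tephritid_gene_stats.tsv",
                     package = "mitoComp")
res <- correlationBattery(stats,
                          c("AT_0F:subst_0F", "R_0F_all:ASD", "AT_4F:ASD"))
res$r <- round(res$r, 3); res$p <- formatPValue(res$p)
res
#>       var1     var2  n      r     p
#> 1    AT_0F subst_0F 13  0.735 0.004
#> 2 R_0F_all      ASD 13  0.983 0.000
#> 3    AT_4F      ASD 13 -0.828 0.000
```

Genes with higher A+T at their 0-fold (non-synonymous) sites substitute
faster at those sites (r = 0.735) and diverge more at the protein level;
high A+T at 4-fold sites marks the conserved genes (r = −0.828).

```r
# the same statistics on simulated data with known per-class rates
cfg <- simulationConfig(seed = 1)          # rates 0.02 / 0.2 / 0.8 per class
o   <- simulateOrthologSet(cfg, "cox1")
round(geneClassStats(o$sequences, gene = "cox1")[
    , c("subst_0F", "subst_4F", "R_0F_all", "ASD")], 3)
#>   subst_0F subst_4F R_0F_all   ASD
#> 1    0.038    1.708     0.16 0.194
```

The estimated frequencies bracket the configured expectations (2 × rate =
0.04 and 1.6 on a star phylogeny).

A thin command-line front end over the same functions ships in
`inst/cli/mitocomp.R` (subcommands `boundaries`, `composition`, `rscu`,
`degeneracy`, `divergence`, `correlate`, `cr-scan`, `simulate`,
`pipeline`).

## Documentation

The methods vignette (`vignettes/mitocomp-methods.Rmd`) describes the
models, estimators, parameter choices and the simulator's design in
detail, including its known limitations.
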