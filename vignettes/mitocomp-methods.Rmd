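---
title: "Methods: degenerate-site divergence analysis of circular mitogenomes"
author: "mitoComp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degenerate-site divergence analysis of circular mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoComp)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the design decisions made where
more than one defensible choice existed.

## Coordinate model

A mitogenome is a closed circle. All coordinates are **1-based inclusive**
positions on the majority (J) strand; minority-strand (N) features are
stored with J-strand coordinates and extracted as reverse complements. A
feature with `end < start` wraps the replication origin and has length
`end + L − start + 1`. The gap between adjacent features *f* and *g* in
genomic order is `start(g) − end(f) − 1`; the pair that closes the circle
uses `start(first) + L − end(last) − 1`. Positive gaps are intergenic
spacers, negative gaps overlaps, zero abutting genes. Because the control
region is an ordinary feature, it creates no artificial gap, and on a fully
annotated circle the lengths and signed gaps must sum to the genome length
— `computeBoundaries()` output satisfies this identity by construction and
the test suite asserts it on the bundled 16,043 bp annotation.

Annotation tables are read from a TSV dialect (`gene`, `strand`, `start`,
`end`, optional `kind`, `size`, `anticodon`) or from GenBank flat files.
Strand tokens `F`/`R`, common in published tables, normalise to `J`/`N`. A
`size` column, when present, is cross-checked against the coordinates and a
mismatch is a hard error naming the feature: published tables do contain
arithmetic slips, and silently trusting either number would corrupt every
downstream total. Feature containment is likewise rejected rather than
merged, since overlapping genes are common in these genomes but one gene
fully containing another almost always signals a corrupted table.

## Genetic code and degeneracy classes

The default code is NCBI translation table 5 (invertebrate mitochondrial:
ATA = Met, TGA = Trp, AGA/AGG = Ser, stops TAA/TAG, hence 62 sense
codons), configurable to any table Biostrings knows. A codon position is
**4-fold** degenerate when all four nucleotides there preserve the amino
acid, **0-fold** when only the observed one does, **2-fold** otherwise.
3-fold positions (e.g. Ile ATH under the standard code) are binned with
2-fold: the three-way classification used in mitogenome work has no 3-fold
bin, and table 5 produces none anyway. The classifier is a precomputed
lookup over all 64 codons; the test suite checks it exhaustively against a
brute-force translate-all-alternatives oracle for tables 1, 2 and 5, and
verifies that under table 5 every second codon position is 0-fold.

Across a codon-aligned ortholog set, per-site classes can disagree between
species once sequences diverge. The default **concordance rule** assigns a
site a class only when every species agrees on its fold; discordant sites
are excluded from class statistics. This is the conservative choice: it
never attributes a substitution to a class the site only holds in some
taxa. A `reference` rule (classes taken from one chosen species) is
available for sensitivity analysis. Class-wise A+T content is computed per
species over the class's sites and then summarised as mean ± sample SD
(n − 1) across species, i.e. the per-species-then-average convention that
matches tables reporting "mean ± SD over N taxa"; pooling sites across
species first is the alternative reading and gives slightly different
numbers.

## Divergence estimators

Within one class, each species pair contributes the p-distance over the
class's sites (gap/N positions deleted pairwise) and its Jukes–Cantor
correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. The class's
**substitution frequency** is the mean corrected distance over all
unordered pairs. JC rather than raw p is used because class-wise
frequencies above 1 substitution per site occur in real data (fast 4-fold
sites) and are impossible without a multiple-hit correction; JC is the
minimal such correction. Pairs at or beyond the JC saturation point
(p ≥ 0.75) are excluded with a warning, and an all-saturated class is an
error rather than a number.

**Substitution-count ratios** `R_class` divide the summed raw pairwise
difference counts at a class by the summed counts over all three classes.
Raw counts, not corrected distances, keep the ratios well defined near
saturation, and make the three ratios sum to exactly 1 on every input.

Protein divergence uses the **Poisson correction**
$d = -\ln(1 - p)$ over pairwise-deleted residues, and the per-gene summary
(ASD) is the mean over all pairs. Saturation (p = 1) is an error: the
distance is infinite and averaging it would be meaningless.

Codon alignments are taken as given. The package deliberately contains no
aligner: mitochondrial PCG ortholog sets are conventionally aligned by
back-translating a protein alignment, and which aligner to trust is a
question upstream of this package.

## Correlation analysis

`pearsonCorrelation()` reports sample Pearson r with the classical
two-tailed P from $t = r\sqrt{(n-2)/(1-r^2)}$ on n − 2 degrees of freedom
(delegated to `stats::cor.test`). `correlationBattery()` runs named column
pairs of a per-gene table, dropping genes with undefined values pairwise.
No multiple-testing correction is applied — the battery mirrors how such
tables are conventionally reported, and readers can apply their own. P
values print at three decimals with values below 0.0005 shown as
`0.000`; r prints at three decimals. Full precision is always available in
the returned data frames.

## Control-region scanners

All scanners are pure string functions over the J-strand sequence,
reporting 1-based J-strand coordinates (a `genomeStart` offset maps a
region's local coordinates into genome coordinates).

* **Poly-T**: maximal runs of T with length ≥ `minRun` (default 5; runs of
  A are poly-T on the N strand and reported with strand `N`).
* **[TA(A)]n**: downstream of each J-strand poly-T (window default 50 bp),
  the longest segment decomposable into TA/TAA units, greedy left-to-right
  preferring the longer TAA unit on ties; at least 3 units.
* **Purine-rich blocks**: merged maximal windows (default 10 bp) with G+A
  fraction ≥ `minFrac` (default 0.75); the reported score is the merged
  block's purine fraction.
* **Tandem repeats**: exact-match arrays only, unit lengths
  `minUnit..maxUnit`, at least `minCopies` full copies, maximally extended
  including a fractional trailing copy. Overlapping candidate arrays are
  collapsed to the highest-copy-number representative, with overlap judged
  on the full-copy core span so that a fractional tail cannot let an
  unrelated neighbouring array shadow a genuine one. Mismatch-tolerant
  (alignment-scored) repeat detection is a different published algorithm
  and out of scope.
* **Counterpart search**: ungapped sliding of the query over both subject
  strands; all `minLen`-bp windows at identity ≥ `minIdentity` (default
  0.70, chosen from the conservation range typical of spacer counterparts)
  are found and consecutive qualifying windows of one offset merge into a
  maximal match; N-strand coordinates map back to the subject's forward
  strand.
* **Hairpins**: perfect stems only, Watson–Crick pairs (no G·U), stem ≥
  `minStem` (≥ 3) enclosing a loop of 3–12 bp; each loop placement is
  extended outward maximally.

Each scanner has a naive brute-force counterpart in the test suite and
must agree with it on batches of random sequences; hairpin counts are also
checked to be invariant under reverse complement of the whole sequence.

## The synthetic-data generator

`simulateGenome()` lays configured features head to tail around a circle
with planted signed gaps and assembles a control region carrying a poly-T
run, a TA(A)n stretch, a purine-rich block, an exact tandem repeat and a
copy of one spacer, all at recorded coordinates; guard bases around each
planted motif keep it maximal exactly there. The ground truth is returned
alongside, so boundary accounting and every scanner can be validated
without any external data.

`simulateOrthologSet()` draws a root CDS whose codons are sampled with
per-class A+T bias — each sense codon's weight is the product over its
positions of a class-conditional nucleotide distribution (A and T share
the class bias equally; G and C the remainder) — then evolves each species
independently from the root (a **star phylogeny**). Each site receives a
Poisson number of substitution events at its class's rate; each event
replaces the base uniformly with one of the other three, redrawn if the
codon would become a stop, so sequences stay translatable.

Design rationale. A star rather than a tree keeps expectations analytic:
the expected pairwise divergence at a class is exactly twice the tip rate,
which is what the recovery tests assert. The uniform replacement kernel
makes the process exactly the Jukes–Cantor chain, so the JC estimator is
consistent for the planted rates; an A+T-biased replacement kernel
(stationary frequencies equal to the class bias) was evaluated and rejected
because it makes JC underestimate high rates by ~17% at strong bias,
destroying the clean rate-recovery contract. The cost of that choice is a
known limitation: the planted A+T bias lives in the root and **erodes
toward 50% at heavily substituted classes**, so the generator does not
emulate the sustained mutational A+T pressure that real mitogenomes
experience. Consequences: class-wise A+T in heavily evolved synthetic data
is lower than the configured bias, and cross-gene bias–rate correlations
are only tested at modest rates (≤ 0.4 substitutions/site) where the root
signal survives. Passing tests therefore demonstrate correct accounting
and estimation, not that the simulator reproduces mutational bias — real
data keep features (AT-pressure, rate heterogeneity within classes,
indels, non-independence through phylogeny) the generator deliberately
omits.

Default conditions: 10 species, the 13 mitochondrial PCGs at their typical
codon counts, per-class rates 0.02/0.2/0.8 expected substitutions per site
(0-, 2-, 4-fold) with A+T biases 0.66/0.78/0.79, and a ~1.1 kb control
region with a 24 bp poly-T. Recovery checks run 100 replicates of a
500-codon gene across 10 species — large enough that the per-class JC
means are stable to a few percent, small enough to run comfortably inside
a routine test session. All randomness flows from one integer seed;
per-gene streams are derived deterministically from it, and identical
configurations reproduce byte-identical output.

## Numerical conventions and degenerate inputs

* Percentages print at 1 decimal, r at 3 decimals, P at 3 decimals with a
  `0.000` floor — all with **half-up** rounding (`roundHalfUp()`), the
  convention of printed tables; returned values are never rounded.
* A class or codon family with zero observations yields `NA` (undefined),
  never 0: a zero would silently enter means and correlations.
* Codons containing N are skipped (with a message) in classification and
  codon counting; gap/N sites are deleted pairwise in all distances.
* An internal stop codon in a CDS is an error naming the codon index;
  terminal complete stops and 1–2 nt incomplete stops are trimmed before
  classification.
* RSCU excludes stop codons by default; `includeStops = TRUE` scores them
  as their own family, reproducing the layout of published codon-usage
  tables whose stop-codon handling is not otherwise documented.
* Empty site sets, empty sequences, n < 3 correlations and zero-variance
  inputs are errors, not NA results.

## Known limitations

Besides the simulator's neutral-kernel limitation above: the package does
not align sequences, predict tRNA structures, fold RNA thermodynamically,
estimate dN/dS by maximum likelihood or build trees — those belong to
dedicated tools. Genome-scale published quantities (region compositions,
RSCU tables, codon-class ratios, motif coordinates) can only be recomputed
from the deposited genome sequences, which are not redistributed with the
package; `inst/scripts/fetch-accessions.R` retrieves them when network
access is available.
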