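---
title: "Quantifying phenazine producers and degraders in shotgun metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phenazine producers and degraders in shotgun metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phzscan)
```

## The estimation problem

Phenazines are redox-active bacterial antibiotics that can protect crops
from fungal disease. Whether they matter in a given soil or rhizosphere
depends on how abundant the bacteria that synthesize them (phz+ bacteria)
and the bacteria that degrade them are. Shotgun metagenomes can answer this
question culture-free, but raw gene counts are confounded: samples differ
in sequencing depth, in the amount of non-bacterial DNA (plant host,
fungi), and in how much of the community is represented in reference
databases. Normalizing by library size is therefore unreliable.

`phzscan` implements a marker-normalized estimator. Two gene panels are
quantified side by side:

* **Trait panel.** The core phenazine biosynthesis genes, quantified as
  five merged families: phzA_B (phzA and phzB share highly similar
  sequences and are merged), phzD, phzE, phzF and phzG. phzC is excluded
  from the catalog outright because near-identical copies occur in
  non-producer genomes and would create false positive signal. Degradation
  is tracked by two single-gene traits, phdA (phenazine-1-carboxylic acid
  degradation) and podA (pyocyanin demethylation), reported separately.
* **Marker panel.** 25 ubiquitous single-copy genes (a bac120-style set)
  that together measure "total bacteria" robustly across community
  compositions and host-DNA loads.

For a sample, reads are translated in six frames and mapped to the catalog
proteins with best-hit semantics (one target per read, ties broken by
database order). Hits below 80% amino-acid identity are discarded. Counts
are pooled per gene family and size-normalized to reads per kilobase:

$$\mathrm{RPK}_f = \frac{n_f}{\bar{L}_f \cdot 3 / 1000}$$

where $n_f$ is the family read count and $\bar{L}_f$ the family mean
protein length in amino acids (nucleotide-equivalent kilobases; since the
same convention is used in numerator and denominator the unit choice
cancels in the final ratio). The sample is then summarized as

$$\hat{p} = \frac{\mathrm{median}\,\mathrm{RPK}_{\text{phz families}}}
                 {\mathrm{median}\,\mathrm{RPK}_{\text{25 markers}}}$$

Because biosynthesis genes are almost always single-copy, $\hat{p}$ is
interpreted as the fraction of bacteria carrying the trait. The median
(not the mean) makes both scores robust to non-specific signal: the
producer score is exactly zero unless at least three of the five families
carry hits, and inflating one or two marker families arbitrarily leaves
the baseline unchanged. Degrader fractions use the single gene's RPK over
the same marker baseline, so phdA and podA give independent estimates.

Samples are classified as *phz+ rich* at $\hat{p} \ge 0.25\%$ and *high*
at $\hat{p} \ge 0.5\%$ (both inclusive).

## The translated search

Reads are nucleotide; references are proteins. The package ships a
self-contained translated search (`best_hit_search()`) sufficient for
simulation-scale work, and a parser for external DIAMOND/BLAST tabular
output (`parse_hit_table()`) for production-scale mapping; both feed the
same quantification code.

The internal aligner translates each read in all six frames (standard
code, stops as `*`, `N` as `X`, which never counts as a match), finds
exact amino-acid k-mer seeds shared with catalog proteins, and extends
each seed with banded affine Smith-Waterman (BLOSUM62, gap open 11,
extension 1, band half-width 3 diagonals around the seed). The best
alignment across frames and targets wins; score ties go to the earliest
catalog protein, mirroring `-k 1` best-hit behaviour. Alignments shorter
than 15 aligned columns are dropped as micro-hit noise. Percent identity
is matches over aligned columns (the BLAST `pident` convention), and the
80% filter keeps the boundary: only strictly lower identities are
discarded.

Two parameter choices deserve a note:

* **Seed length 6.** With a catalog of a few dozen families, 5-mer seeds
  admit a steady trickle of spurious sub-threshold alignments from
  non-coding sequence and roughly double the runtime; 6-mers produce none
  on the benchmark fixtures while leaving sensitivity at 10% divergence
  essentially perfect (a 50-residue read at 10% divergence retains an
  exact 6-mer with probability well above 0.99). The test suite pins the
  aligner to an exhaustive Smith-Waterman oracle (Biostrings
  `pairwiseAlignment`, identical matrix and gap costs) on instances of up
  to a couple hundred reads.
* **Band half-width 3.** Error-free simulated reads never need gaps, and
  at 100-150 nt even real reads rarely tolerate more than a residue or
  two of indel offset before the alignment dies under affine costs. The
  band makes per-read cost linear and is configurable.

## The simulator and what it does (not) emulate

`make_synthetic_references()` builds the whole fixture universe from a
seed: random ancestor proteins per family (150-450 aa), catalog-side
variants per trait-carrying species (15% between-species divergence, so
species attribution of trait hits stays unambiguous), and genomes that
embed each species' gene copies at a controlled divergence from the
catalog (10% for trait genes by default, half that for markers —
universal single-copy markers are slow-evolving in real catalogs, which
is precisely why they work as a baseline). Genes are reverse-translated
with random synonymous codons, placed on random strands with random
intergenic spacers, and all genomes are padded to one common length so a
species' read fraction equals its cell fraction and the single-copy
interpretation is exact.

`compose_community()` fixes the total producer fraction exactly, splits
it randomly among the chosen producers, draws the degrader frequency, and
spreads the remainder over 28 background species with a symmetric
Dirichlet(1) draw, re-randomized per replicate. (The underlying study
states that background abundances were "randomly set" without naming a
distribution; Dirichlet(1) — uniform on the simplex — is the neutral
choice.) `sample_reads()` realizes counts by largest-remainder rounding
(ground truth exact to 1/library), then samples error-free 150 nt
fragments uniformly with uniform strand. Reads are error-free because the
validation design for the estimator isolates database divergence, the
factor the identity threshold is meant to absorb; a uniform substitution
mode is not provided, and read-simulator error profiles are out of scope.

What the simulator does **not** emulate: real genome size variation
(equal lengths by construction), sequencing error and quality trimming,
paralogy and horizontal transfer inside the background, multi-copy
trait operons, and relatedness between background species and producers.
A green benchmark therefore demonstrates the estimator's arithmetic,
normalization and detection behaviour under controlled divergence — not
robustness to every artifact of field data.

The degrader frequency in factorial designs is drawn log-uniformly from
0.05% to 5% per community (the study describes only a "randomly generated
frequency"; a log-uniform gradient covers the dynamic range evenly for
the per-gene recovery analysis).

## The factorial benchmark

`factorial_design()` reproduces the full validation grid: coverages of 5,
10, 15 and 20 million reads; producer abundances 0, 0.1, 0.25, 0.5, 1,
1.5, 2.5, 3.5 and 5 percent; three producer combinations (each producer
alone, both mixed); twelve replicates — 1296 communities, 48 per
(combination x abundance) cell pooled over coverages.

Routine validation uses `desk_design()`: coverages of 0.5M and 1M reads,
abundances 0, 0.1, 0.25, 0.5, 1, 2.5 and 5 percent, all three
combinations, three replicates — 126 communities and roughly 95M reads
total, which one CPU core processes in minutes. These problem sizes are
the package's standing test conditions; the full-scale grid remains one
function call away.

`accuracy_metrics()` reports the Pearson correlation between known and
estimated fractions, the per-species error distribution restricted to
spikes above 0.1%, the maximum estimate across negative controls (exactly
zero with error-free reads, since background genomes contain no trait
loci), and the **detection limit**, operationalized as the lowest
designed abundance whose replicate estimates all strictly exceed that
maximum. The underlying study reports the outcome (0.1% detectable) but
not a criterion; all-replicates-strictly-above is the conservative
reading. On the desk-scale design the estimator reaches r >= 0.99 and a
detection limit of 0.1%, matching the full-scale validation.

Mixed-producer communities are resolved by splitting the total estimate
according to each producer's share of size-normalized trait signal, so
per-producer estimates sum to the total by construction.

## Survey aggregation

`quantify_batch()` drives the estimator over many samples and joins
habitat metadata (two classes, soil and rhizosphere, plus a free-text
sub-habitat). `aggregate_by_habitat()` reports per-class means and
medians, the fold difference of class means (mean-of-samples, not pooled
reads — the two differ when library sizes vary), a two-sided Wilcoxon
rank-sum test with normal approximation and tie correction, and the
enrichment of high-phz samples between classes. `taxon_habitat_matrix()`
pools hit-level, size-normalized trait signal across all samples of a
habitat before renormalizing — pooling (rather than averaging per-sample
breakdowns) weights samples by their trait content and matches how
habitat-level taxonomic bars are usually drawn; per-sample averaging is
available as an option.

Field-survey quantities from real accession data (wheat-rhizosphere
levels, the 807-sample habitat statistics) require the external samples
themselves and are deliberately outside the test surface; the survey
layer is validated on seeded fixtures with designed contrasts.

## Numerical and degenerate-input conventions

* Ties in best-hit assignment: catalog (database) order, first occurrence
  wins; within one protein, lower frame then lower diagonal — fully
  deterministic, byte-identical across runs.
* Largest-remainder rounding breaks remainder ties by member index.
* `trait_fraction()` errors on a zero marker score ("no bacterial
  signal") rather than returning Inf; fractions above 1 are reported with
  a warning, never clamped.
* Taxon breakdowns omit zero-signal taxa and return an empty vector (not
  an error) when no trait hits exist; non-empty breakdowns sum to 1
  within 1e-12.
* Reads shorter than one codon translate to six empty peptides; sequence
  characters outside `{A,C,G,T,N}` are an error.
* All randomness flows through explicit integer seeds; generator
  functions restore the caller's RNG state.

## Limitations

The estimator measures DNA signal: it says nothing about whether the
producers are metabolically active. Interpretation as a cell fraction
rests on the single-copy assumption and, across species, on genome sizes
being comparable; the simulator enforces equal genome lengths, so its
benchmarks do not probe genome-size bias. The internal aligner is a
desk-scale tool — for hundreds of millions of reads against thousands of
reference proteins, run DIAMOND externally and feed the tabular output to
`parse_hit_table()`.
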