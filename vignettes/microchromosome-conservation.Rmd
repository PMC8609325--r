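---
title: "Microchromosome conservation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microchromosome conservation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microchrom)
```

## The problem

Bird and reptile genomes are split into a handful of large macrochromosomes
and dozens of tiny, gene-dense, GC-rich microchromosomes. Across hundreds of
millions of years the microchromosome complement is remarkably stable:
individual microchromosomes keep a 1:1 correspondence between distantly
related species, and when they disappear from a karyotype they almost always
do so by fusing — with each other, or onto the ends or centromeres of
macrochromosomes — rather than by being lost. `microchrom` implements the
comparative pipeline needed to see this from data: pairwise alignment chains
are reduced to syntenic blocks, chromosomes are classified by a
clade-specific size threshold, micro-to-micro homology is quantified,
fusion/fission events are called per chromosome, and Hi-C contact maps are
partitioned by ancestral state to ask whether chromatin behaviour follows
chromosome class or chromosome history.

Because real inputs are multi-gigabyte assemblies and cluster-scale
alignment runs, the package ships a seeded karyotype-evolution simulator
that generates every input format with a known ground truth. Every claim the
package makes about its own correctness is a property checked against that
ground truth or against a brute-force oracle.

## Chromosome classification

A chromosome is a microchromosome iff its length is strictly below the
clade threshold; a length exactly at the threshold is a macrochromosome.
The canonical threshold for birds and snakes is 35 Mb; clades with
rearranged genomes need larger values (turtles 45 Mb, rearranged lizards
50 Mb, tegu 75 Mb, alligator 96 Mb), which is why the threshold is a
per-karyotype parameter rather than a constant. Where published karyotype
work assigns a class that contradicts assembly length, an explicit
`chrom_class` column wins over the size rule.

GC content is computed over unambiguous A/C/G/T only; Ns and IUPAC
ambiguity codes are excluded from the denominator, and soft-masked
lowercase counts normally (masking marks repeats, not missing data). Gene
density is genes per Mb.

## From chains to syntenic blocks

Chains are read and written in the UCSC dialect with 0-based half-open
coordinates; negative-strand query coordinates stay on the
reverse-complemented sequence as in the format, with
`chain_query_forward()` as the conversion helper.

The netting step is a single-level greedy cover: chains are visited in
descending score (ties by ascending chain id) and accepted iff their span
overlaps previously accepted spans by at most `overlap_tol` bp on *both*
genomes. With the default `overlap_tol = 0` accepted blocks are strictly
non-overlapping on each genome, which makes every downstream statistic
well defined. This deliberately reduces the hierarchical net of the
original tools to its top level: the homology statistics downstream consume
only top-level blocks, and a single-level greedy rule is simple enough to
verify exhaustively against a brute-force re-derivation (which the test
suite does on hundreds of random instances). Note the greedy
highest-score-first rule is the field's netting semantics, not a maximum-
weight interval selection — a single high-scoring chain can displace two
disjoint lower-scoring chains whose combined score is higher; we follow the
netting semantics.

Blocks below a minimum aligned length are discarded before analysis:
100 kb for vertebrate-scale comparisons, 5 kb for compact invertebrate
genomes such as amphioxus. Both values are exposed as plain parameters.

## Micro-to-micro homology

The conservation statistic is the fraction of a query species'
microchromosome alignment that lands on target microchromosomes, with each
block weighted by its aligned bases. Length-weighting is the only choice
that makes the statistic invariant to how an aligner happens to fragment a
chain — splitting a block into abutting halves leaves the value unchanged,
while a count-weighted version drifts (both properties are tested). A count
mode is still exposed for diagnostic use. The query-by-target matrix of
these fractions is asymmetric whenever one lineage has fused
microchromosomes into macrochromosomes: querying *from* the fused lineage,
its surviving micros still match ancestral micros (high fraction), while
querying from the ancestor, the fused material now lands on macros (low
fraction). The simulator reproduces this asymmetry deterministically, and
the acceptance suite checks it across 20 seeds.

The matrix diagonal is fixed at 1 by convention (self-alignment is not
computed), and species pairs without alignment data are `NA`, never 0 — an
absent comparison is not evidence of non-conservation.

## Event calling

For each derived chromosome, the ancestral composition (which query
chromosomes contribute, how much, where) feeds a decision cascade:
conserved 1:1; micro–micro fusion; macro–micro fusion (terminal or
centric); macro–macro fusion; fission; otherwise unresolved. The
parameters that matter:

* `f_intact` (default 0.8): reciprocal coverage needed to call a
  chromosome "intact". Both directions are required — the target must be
  mostly explained by the ancestor *and* the ancestor mostly present in the
  target — because repeat expansion inflates a derived chromosome without
  changing its identity, while a fission fragment explains its target
  completely yet covers only part of its ancestor. The 0.8 default
  tolerates the ~5% alignment loss typical of fragmented chains plus
  moderate expansion.
* `d_term` (default `min(5 Mb, 10%` of the target `)`): a fused micro reads
  as *terminal* when the gap between its span's outer edge and the nearest
  chromosome end is at most `d_term`. The distance is measured from the
  span's edge, not over the whole span, so a 10-Mb micro fused flush to a
  telomere is terminal even with `d_term = 5 Mb`.
* Centromeres are optional. A Robertsonian (centric) fusion produces a
  micro that is a whole chromosome arm — which is also positionally
  terminal, so when a centromere is supplied the whole-arm test runs
  *first*; without one, chain data cannot separate the two and centric
  fusions surface under the terminal label.

Calls are deterministic given blocks and parameters. On simulated
histories (9 macros + 30 micros, 10 events drawn from micro–micro fusion,
terminal macro–micro fusion and fission, default fragmentation noise) the
caller reaches exact-type recall and precision ≥ 0.9 across 20 seeds and
1.0 at zero noise — these thresholds are the package's own acceptance
surface, not an empirical literature value.

The four-way map labels each block's target interval by the (query class,
target class) pair — `macro`, `micro`, `new_macro` (micro fused into a
macro), `new_micro` (macro fragment now micro-sized) — resolving overlaps
in favour of the higher-scoring, then longer, block so that every
classified base carries exactly one state.

## Hi-C statistics

Contact matrices enter as 7-column GInteractions text at 50-kb bins
(origin scaffold/start/end, target scaffold/start/end, interaction count);
the reader enforces exactly seven columns and folds duplicate symmetric
entries. Matrices are assumed pre-normalized upstream; no balancing is
performed. Analysis restricts to the `expected_n` largest scaffolds so
unplaced fragments do not dilute chromosome-level means.

P(s) is estimated as the mean count per intra-chromosomal bin pair within
each distance bin, zeros included, over 30 logarithmic bins from one bin
width to 1e8 bp. A unit-sum "probability" mode is provided for when curves
of classes with very different pair counts must be overlaid. Two
estimator-validity rules are applied in the package's own analyses: the
first diagonal (separation = one bin) is excluded via `min_dist = 1e5`,
since in real Hi-C it is dominated by self-ligation artifacts; and curve
bins supported by fewer than ~100 valid pairs are not used for ordering
comparisons or exponent fits, because a mean over a handful of Poisson
draws is noise. Decay exponents come from a log–log least-squares fit over
a stated distance window (macros 0.1–20 Mb; micros 0.1–5 Mb, inside the
span every microchromosome can reach).

## The simulator

The generator's defaults are the study conditions. The ancestor has 9
macrochromosomes (45–210 Mb) and 30 microchromosomes (4–30 Mb) under a
35-Mb threshold, micro GC elevated by 0.06 over a 0.41 macro mean
(sd 0.01 per chromosome), and gene densities of ~40 genes/Mb on micros
versus ~17 on macros — the documented contrast for chicken. Events
maintain an exact segment map from every derived interval to its ancestral
source, so ground truth is a construction, not an estimate; derived GC is
the length-weighted mean of its sources by definition.

Chain emission fragments each conserved segment with Poisson-distributed
break points (default 0.5 breaks/Mb) and removes a total of `gap_frac`
(default 5%) of the segment at those breaks — a geometric splitting model
that produces realistically fragmented chains while keeping total aligned
length accountable to within the configured gap fraction.

Simulated Hi-C draws Poisson counts around a power-law expectation
`intra_scale * d^(-alpha)` within chromosomes (`alpha_macro = 1.5`,
`alpha_micro = 1.0`, so micros are the more compact, slower-decaying
class) and around `trans_base * f(a) f(b)` between chromosomes, where the
per-chromosome propensity `f` is `sqrt(k)` for micros (`k = 3` by
default). The multiplicative propensity model gives micro–micro pairs a
k-fold enrichment over macro–macro with mixed pairs at the geometric
midpoint — matching the graded ordering seen in real bird contact maps,
where micro–macro contacts are intermediate rather than equal to
macro–macro. Trans counts are drawn with the thinning identity (a single
Poisson total placed uniformly over cells equals independent Poisson
cells), which keeps full-genome simulation tractable.

What the simulator does *not* emulate: inversions and translocations
(orientation is always preserved; inversion calling is out of scope),
repeat sequence structure (expansion inserts unaligned length, not TE
sequence), alignment artifacts such as paralogy-induced many-to-many
chains, and Hi-C biases (GC/mappability bias, balancing artifacts, TADs,
compartments). Passing tests therefore demonstrate correctness of the
statistics and the callers under the stated generative model — not
robustness to every pathology of real alignments or real contact maps.

## Problem sizes

The test and acceptance runs use the full 39-chromosome karyotype for
chain-based analyses, and a reduced Hi-C karyotype (2 macros of 36–60 Mb,
6 micros of 5–15 Mb, ~3,000 bins at 50 kb) chosen so a simulated matrix
still spans two decades of genomic separation while a 20-seed study
completes in minutes on one core. Oracle-equivalence checks run on ≥200
random instances of ≤15 chains / ≤100 bins, where exhaustive enumeration
is feasible.

## Worked example

```{r example, eval = FALSE}
anc <- simulate_ancestor(seed = 1)
history <- apply_events(anc, n_events = 10, seed = 2)
blocks <- reciprocal_best(filter_chains(emit_chains(history, seed = 3), 1e5))

micro_fraction(blocks, anc, history$derived)
calls <- call_events(blocks, anc, history$derived)
event_table(calls)
score_event_recovery(calls, history)
```

The numbered scripts under `analysis/` run the same pipeline from files on
disk (karyotype TSV, UCSC chain, GInteractions), writing tables under
`results/`.

## Known limitations

* Netting is single-level; nested nets (inversions inside larger blocks)
  are collapsed into their parent or rejected.
* Centric versus terminal fusion is undecidable without centromere
  positions; the merged behaviour is deliberate.
* The four-way map inherits the block filter: short conserved fragments
  below `min_len` are invisible to it.
* P(s) in "probability" mode depends on the distance-bin scheme; compare
  curves only under identical binning.
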