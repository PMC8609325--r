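# microchrom

Comparative-genomics toolkit for the evolutionary fate of
**microchromosomes** — the tiny (< ~35 Mb), GC-rich, gene-dense
chromosomes that dominate bird and reptile karyotypes and stay conserved
almost base-for-base across hundreds of millions of years, until they
disappear by fusing with each other or onto macrochromosomes.

The package takes the standard artifacts of a whole-genome comparison and
turns them into the statistics of microchromosome conservation:

* **UCSC chain files** → reciprocal-best **syntenic blocks** via
  single-level greedy netting (descending score, non-overlapping on both
  genomes), with the usual 100-kb (vertebrate) / 5-kb (amphioxus-scale)
  length filters;
* **karyotype tables** → macro/micro classification by a clade-specific
  size threshold (micro iff length < threshold; 35 Mb for birds and
  snakes, up to 96 Mb for alligator), plus per-chromosome GC and gene
  density;
* blocks + karyotypes → the **micro-to-micro fraction**: the
  length-weighted share of a query species' microchromosome alignment
  landing on target microchromosomes,

  `F(q,t) = Σ aligned_bp(micro→micro) / Σ aligned_bp(micro→anything)`,

  assembled into the asymmetric query × target conservation matrix;
* blocks per derived chromosome → **fusion/fission event calls**
  (conserved, micro–micro fusion, terminal/centric macro–micro fusion,
  macro–macro fusion, fission) and the **four-way ancestral-state map**
  (macro / micro / new_macro / new_micro);
* **7-column GInteractions** Hi-C matrices at 50-kb bins →
  inter-scaffold interaction heat maps, class-partitioned
  distance-dependent contact probabilities **P(s)** (mean counts per bin
  pair, log-binned to 1e8 bp) and fitted decay exponents.

A seeded **karyotype-evolution simulator** generates every input format —
karyotype TSV, FASTA, chain, GInteractions — from a known event history,
so the entire pipeline is testable end to end without any genome download.

## Worked example

```r
library(microchrom)

anc     <- simulate_ancestor(seed = 1)             # 9 macros + 30 micros
history <- apply_events(anc, n_events = 10, seed = 2)
blocks  <- reciprocal_best(filter_chains(emit_chains(history, seed = 3), 1e5))

calls <- call_events(blocks, anc, history$derived)
event_table(calls)
#>             conserved_micro             conserved_macro
#>                          22                           1
#>          micro_micro_fusion macro_micro_fusion_terminal
#>                           2                           4
#>  macro_micro_fusion_centric          macro_macro_fusion
#>                           0                           0
#>           fission_new_micro           fission_new_macro
#>                           1                           7
#>                  unresolved
#>                           0
unlist(score_event_recovery(calls, history))
#>    recall precision   n_truth  n_called
#>         1         1        14        14
```

All 14 simulated rearrangements (two micro–micro fusions, four terminal
macro–micro fusions, and four fissions yielding eight products) are
recovered with their exact type despite default chain-fragmentation noise.

On the Hi-C side (simulated with decay exponents 1.5/1.0 and threefold
micro–micro trans enrichment):

```r
kar <- simulate_ancestor(n_macro = 2, n_micro = 6,
                         macro_size_range = c(36e6, 60e6),
                         micro_size_range = c(5e6, 15e6), seed = 5)
cm  <- simulate_hic(kar, seed = 6)
cur <- ps_curve(cm, kar, min_dist = 1e5)
fit_ps_exponent(cur[cur$class == "macro", ], c(1e5, 2e7))   # 1.49
fit_ps_exponent(cur[cur$class == "micro", ], c(1e5, 1e7))   # 0.99
trans_mean_by_class(cm, kar)
#>    pair_class n_pairs sum_counts      mean
#> 1 macro-macro 4839929    1450364 0.2996664
#> 2 macro-micro 7757192    4028729 0.5193540
#> 3 micro-micro 1752474    1577222 0.8999974
```

The micro P(s) curve sits above the macro curve at every well-supported
separation, and mean trans contact orders micro–micro > macro–micro >
macro–macro, as in real bird contact maps.

The numbered scripts under `analysis/` run the same pipeline from files on
disk (`01_simulate.R` writes all inputs under `results/sim/`; `02`–`05`
classify, net, call events and compute Hi-C statistics, writing tables
under `results/`).

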