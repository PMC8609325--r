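#!/usr/bin/env Rscript
# Reduce the chain set to reciprocal-best syntenic blocks (100-kb filter),
# then quantify micro-to-micro homology in both query directions and emit
# plot-ready resized coordinates.

suppressMessages(library(microchrom))

out <- "results"
anc <- read_karyotype("results/sim/ancestor.karyotype.tsv", 35e6)
der <- read_karyotype("results/sim/derived.karyotype.tsv", 35e6)

chains <- read_chain("results/sim/ancestor_vs_derived.chain")
blocks <- reciprocal_best(filter_chains(chains, 1e5))
message(sprintf("%d chains -> %d syntenic blocks after 100-kb filter",
                length(chains), nrow(blocks)))
blocks_to_bed(blocks, file.path(out, "synteny_blocks.derived.bed"),
              side = "target")

mfm <- micro_fraction_matrix(
  list(list(query = "ancestor", target = "ancestor_derived",
            blocks = blocks),
       list(query = "ancestor_derived", target = "ancestor",
            blocks = invert_blocks(blocks))),
  list(ancestor = anc, ancestor_derived = der))
write_micro_fraction_matrix(mfm, file.path(out, "micro_fraction_matrix.tsv"))
message("micro-to-micro fraction matrix (asymmetry = fused micros):")
print(round(mfm$fraction, 3))

layout <- resize_for_plot(anc, der, blocks)
write.table(layout$blocks, file.path(out, "homology_plot_coords.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
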