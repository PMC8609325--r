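#!/usr/bin/env Rscript
# Classify both genomes with the 35-Mb bird/snake threshold and summarise
# the two hallmarks of microchromosomes: elevated GC and gene density.

suppressMessages(library(microchrom))

out <- "results"
anc <- read_karyotype("results/sim/ancestor.karyotype.tsv",
                      micro_threshold = 35e6)
der <- read_karyotype("results/sim/derived.karyotype.tsv",
                      micro_threshold = 35e6)

tab <- gc_vs_size_table(anc)
tab$genes_per_mb <- gene_density(anc$chromosomes$n_genes,
                                 anc$chromosomes$length)[
                                   match(tab$name, anc$chromosomes$name)]
write.table(tab, file.path(out, "gc_vs_size.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

by_class <- aggregate(cbind(gc, genes_per_mb) ~ chrom_class, data = tab,
                      FUN = mean)
message("per-class means (ancestor):")
print(by_class)
write.table(by_class, file.path(out, "class_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("derived karyotype: %d chromosomes (%d micro)",
                nrow(der$chromosomes),
                sum(der$chromosomes$chrom_class == "micro")))
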