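#!/usr/bin/env Rscript
# Hi-C statistics: inter-scaffold interaction heat map, class-partitioned
# distance-dependent contact probabilities P(s), fitted decay exponents,
# and trans-contact enrichment by chromosome-class pair.

suppressMessages(library(microchrom))

out <- "results"
kar <- read_karyotype("results/sim/hic.karyotype.tsv", 35e6)
cm <- read_ginteractions("results/sim/hic.ginteractions.tsv")
cm <- select_top_scaffolds(cm, kar)

hm <- interaction_heatmap(cm)
write.table(cbind(scaffold = rownames(hm), as.data.frame(hm)),
            file.path(out, "interaction_heatmap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cur <- ps_curve(cm, kar, min_dist = 1e5)
write.table(cur, file.path(out, "ps_curves.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
a_mac <- fit_ps_exponent(cur[cur$class == "macro", ], c(1e5, 2e7))
a_mic <- fit_ps_exponent(cur[cur$class == "micro", ], c(1e5, 5e6))
message(sprintf("fitted P(s) exponents: macro %.2f, micro %.2f", a_mac, a_mic))

tm <- trans_mean_by_class(cm, kar)
write.table(tm, file.path(out, "trans_means.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("mean trans contact by class pair:")
print(tm)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(cur[!is.na(cur$p) & cur$p > 0, ],
              aes(s_mid, p, colour = class)) +
    geom_line() + scale_x_log10() + scale_y_log10() +
    labs(x = "genomic separation s (bp)", y = "P(s)",
         colour = "chromosome class")
  ggsave(file.path(out, "ps_curves.png"), p, width = 6, height = 4, dpi = 150)
}
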