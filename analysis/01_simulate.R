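#!/usr/bin/env Rscript
# Generate one complete simulated study: an ancestral bird-like karyotype
# (9 macros + 30 micros), a derived lineage shaped by 10 fusion/fission
# events, the alignment chains between the two genomes, and a Hi-C contact
# map of a reduced derived-like karyotype. All downstream drivers read the
# files written here.

suppressMessages(library(microchrom))

seed <- 1
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

anc <- simulate_ancestor(seed = seed)
history <- apply_events(anc, n_events = 10, seed = seed + 1)
message("simulated history:")
print(history)

write_karyotype(anc, file.path(out, "ancestor.karyotype.tsv"))
write_karyotype(history$derived, file.path(out, "derived.karyotype.tsv"))
write_event_log(history, file.path(out, "events.json"))

chains <- emit_chains(history, frag_rate = 0.5, gap_frac = 0.05,
                      seed = seed + 2,
                      path = file.path(out, "ancestor_vs_derived.chain"))
message(sprintf("emitted %d chains (%.1f Mb aligned)", length(chains),
                sum(chain_aligned_bp(chains)) / 1e6))

# Hi-C at 50-kb bins on a reduced derived-like karyotype (2 macros + 6
# micros) so the contact map stays desk-sized
hic_kar <- simulate_ancestor(n_macro = 2, n_micro = 6,
                             macro_size_range = c(36e6, 60e6),
                             micro_size_range = c(5e6, 15e6),
                             species = "hic_genome", seed = seed + 3)
cm <- simulate_hic(hic_kar, alpha_macro = 1.5, alpha_micro = 1.0,
                   micro_trans_factor = 3, seed = seed + 4)
print(cm)
write_karyotype(hic_kar, file.path(out, "hic.karyotype.tsv"))
write_ginteractions(cm, file.path(out, "hic.ginteractions.tsv"))
message("inputs written under ", out)
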