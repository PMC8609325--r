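#!/usr/bin/env Rscript
# Call fusion/fission events per derived chromosome from syntenic-block
# composition, compare against the simulator's ground truth, and build the
# four-way ancestral-state region map.

suppressMessages(library(microchrom))

out <- "results"
anc <- read_karyotype("results/sim/ancestor.karyotype.tsv", 35e6)
der <- read_karyotype("results/sim/derived.karyotype.tsv", 35e6)
blocks <- reciprocal_best(filter_chains(
  read_chain("results/sim/ancestor_vs_derived.chain"), 1e5))

calls <- call_events(blocks, anc, der)
write.table(calls, file.path(out, "rearrangement_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("event table:")
print(event_table(calls))

truth <- jsonlite::read_json("results/sim/events.json")
message(sprintf("ground truth: %d events", length(truth$events)))

map <- classify_regions_four_way(blocks, anc, der)
write_region_map(map, file.path(out, "fourway_region_map.bed"))
by_state <- tapply(map$end - map$start, map$state, sum) / 1e6
message("four-way state totals (Mb):")
print(round(by_state, 1))
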