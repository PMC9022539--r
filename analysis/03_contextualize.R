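#!/usr/bin/env Rscript
# Contextualizes the enumerated triads against the simulated expression
# tables (down-down selection with the secondary miRNA required up), then
# removes relationships where gene A is a known direct regulator of gene B.
# The stage-by-stage counts mirror how a real study prunes an enumerated
# relationship list down to a validation set.

suppressPackageStartupMessages(library(coordbio))

triads <- read.delim("results/triads.tsv")
mrna_de <- read_expression("results/data/mrna_de.tsv")
mirna_de <- read_expression("results/data/mirna_de.tsv")
edges <- read_edges("results/data/tf_edges.tsv")

cx <- contextualize(triads, mrna_de, mirna_de, mode = "down_down")
final <- filter_direct_regulation(cx, edges)

write.table(cx, "results/contextualized_triads.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(final, "results/final_triads.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
export_network(final, format = "json", path = "results/network.json")
export_network(final, format = "graphml", path = "results/network.graphml")

message(sprintf("%d enumerated -> %d down-down -> %d after direct-regulation filter",
                nrow(triads), nrow(cx), nrow(final)))
message(sprintf("confidence tiers: %s",
                paste(names(table(final$tier)), table(final$tier),
                      sep = "=", collapse = ", ")))
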