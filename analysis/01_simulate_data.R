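#!/usr/bin/env Rscript
# Builds the synthetic study bundle every later step consumes: a binding-site
# catalog with five planted coordinate-biogenesis triads plus one decoy block
# per triad condition, matched mRNA/miRNA differential-expression tables with
# the planted signature (regulator and secondaries up, targets down), a
# transcription-factor edge covering one planted pair, and a small pathway
# collection over the synthetic genes.

suppressPackageStartupMessages(library(coordbio))

seed <- 20260921L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

g <- generate_catalog(seed = seed)
write_catalog(g$catalog, file.path(out, "catalog.tsv"))
message(sprintf("catalog: %d sites, %d indexed pairs, %d planted triads",
                nrow(g$catalog$sites), nrow(g$catalog$index),
                nrow(g$truth$planted_triads)))

de <- generate_expression(g$truth, noise_sigma = 0.2, seed = seed + 1)
write.table(de$mrna_de, file.path(out, "mrna_de.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(de$mirna_de, file.path(out, "mirna_de.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# gene A of the first planted triad posed as a TF of its gene B: the direct
# regulation filter in step 03 must remove exactly this relationship
tr <- g$truth$planted_triads
edges <- data.frame(source_gene = tr$gene_a[1], target_gene = tr$gene_b[1],
                    relation = "TF")
write.table(edges, file.path(out, "tf_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# pathway collection: one set holding the planted effector genes (gene B),
# one random set, over the full synthetic gene background
set.seed(seed)
bg <- g$truth$genes
gmt <- c(paste(c("effectors", "planted secondary effector genes",
                 unique(tr$gene_b)), collapse = "\t"),
         paste(c("random_set", "random control set",
                 sample(bg, 6)), collapse = "\t"))
writeLines(gmt, file.path(out, "pathways.gmt"))
writeLines(bg, file.path(out, "background.txt"))

write.table(tr, file.path(out, "planted_triads.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote study bundle under ", out)
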