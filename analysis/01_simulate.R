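#!/usr/bin/env Rscript
# Step 1 — generate the synthetic allotetraploid study set.
#
# Builds the default study conditions: 3 homoeologous chromosome pairs
# (A01..A03 / C01..C03) x 60 genes each, 20 accessions (8 resynthesised
# "synthetic", 12 natural), ~12x Poisson depth, HEs biased to chromosome
# ends and towards the C->A direction, plus independent single-gene
# deletions. Writes the reference annotation, homology table, family
# assignment and event truth under results/sim/. Depth tracks are large
# and fully determined by the seed, so downstream steps regenerate them
# with simulate_depth() instead of reading files.

library(panhe)

seed <- 1L
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_study(cfg)
truth <- sim$truth

write_annotation_gff3(truth$annotation, "results/sim/reference.gff3")
write_homology_table(truth$homology, "results/sim/homology.tsv")
write.table(truth$families, "results/sim/families.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth$events, "results/sim/true_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_pav_matrix(truth$truth_pav, "results/sim/truth_pav.tsv")

n_genes <- nrow(truth$annotation$genes)
cat(sprintf("reference: %d chromosomes, %d genes, %d homoeolog pairs\n",
            nrow(truth$annotation$chromosomes), n_genes, n_genes %/% 2L))
cat(sprintf("accessions: %d (%d synthetic)\n", nrow(truth$accessions),
            sum(truth$accessions$class == "synthetic")))
cat(sprintf("true HE events: %d (%.0f%% C->A); single-gene deletions: %d\n",
            nrow(truth$events),
            100 * mean(truth$events$direction == "C->A"),
            sum(lengths(truth$deletions))))
by_class <- table(truth$accessions$class[match(truth$events$accession,
                                               truth$accessions$accession)])
cat("HEs by accession class:",
    paste(names(by_class), by_class, sep = "=", collapse = ", "), "\n")
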