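#!/usr/bin/env Rscript
# Stage 1: simulate the study community.
#
# Generates the default synthetic emulation of the pot experiment — maize
# and watermelon, seeds coated with the Trichoderma inoculant or a control
# coating, 6 replicates each — and writes the OTU table, taxonomy and
# sample metadata that every later stage reads.

suppressPackageStartupMessages(library(rhizonet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
com <- generate_counts(default_scenario(seed))

write_count_table(com$counts, "results/data/counts.tsv")
write_taxonomy(com$taxonomy, "results/data/taxonomy.tsv")
write_sample_metadata(com$metadata, "results/data/metadata.tsv")

ra <- to_relative_abundance(com$counts)
tri <- collapse_genus(com$counts, com$taxonomy, "Trichoderma")
f <- colSums(ra[tri$members, , drop = FALSE])
coated <- com$metadata$treatment == "coated"

cat(sprintf("simulated %d OTUs x %d samples (seed %d)\n",
            nrow(com$counts), ncol(com$counts), seed))
cat(sprintf("planted modules: %s; focal OTUs: %s\n",
            paste(lengths(com$truth$modules), collapse = " + "),
            paste(com$truth$focal_otus, collapse = ", ")))
cat(sprintf("Trichoderma mean relative abundance: %.3f%% coated vs %.3f%% control\n",
            100 * mean(f[coated]), 100 * mean(f[!coated])))
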