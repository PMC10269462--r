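#!/usr/bin/env Rscript
# Stage 3: co-occurrence networks.
#
# One signed Spearman network per (crop, treatment) group under the
# |rho| > 0.8, p < 0.05 edge rule, with the negative-edge proportion and the
# natural-connectivity robustness curve (random node removal, 1%-60%).
# Coating is expected to raise the negative-edge share and, through the
# focal module, network redundancy.

suppressPackageStartupMessages(library(rhizonet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1

counts <- read_count_table("results/data/counts.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")
meta <- meta[match(colnames(counts), meta$sample_id), ]
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

groups <- split(meta$sample_id, paste(meta$crop, meta$treatment, sep = "_"))
summary_rows <- list()
for (g in names(groups)) {
  net <- suppressWarnings(group_network(counts, groups[[g]], group = g))
  write_edge_list(net, sprintf("results/tables/network_%s_edges.tsv", g))
  rc <- robustness_curve(net, fractions = c(0.01, seq(0.05, 0.6, 0.05)),
                         n_reps = 30, seed = split_seed(seed, g))
  write.table(rc$curve, sprintf("results/tables/robustness_%s.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary_rows[[g]] <- data.frame(
    group = g, n_nodes = length(net$nodes), n_edges = nrow(net$edges),
    negative_edge_ratio = suppressWarnings(negative_edge_ratio(net)),
    natural_connectivity = natural_connectivity(net),
    robustness_auc = robustness_auc(rc))
}
summ <- do.call(rbind, summary_rows)
write.table(summ, "results/tables/network_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(summ)))
  cat(sprintf("%-20s %3d nodes %4d edges  neg ratio %.3f  robustness AUC %.3f\n",
              summ$group[i], summ$n_nodes[i], summ$n_edges[i],
              summ$negative_edge_ratio[i], summ$robustness_auc[i]))
for (crop in unique(meta$crop)) {
  d <- summ[startsWith(summ$group, crop), ]
  cat(sprintf("%s: negative-edge ratio coated %s control; robustness AUC coated %s control\n",
              crop,
              ifelse(diff(d$negative_edge_ratio[order(d$group)]) < 0, ">", "<="),
              ifelse(diff(d$robustness_auc[order(d$group)]) < 0, ">", "<=")))
}
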