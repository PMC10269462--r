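#!/usr/bin/env Rscript
# Stage 4: modules, eigengenes, traits and hubs.
#
# Detects network modules per group, summarises each labelled module by its
# eigengene (first PC of log-standardised member abundances), correlates
# eigengenes with the plant traits and soil enzyme activities of the same
# samples (Pearson, BH-corrected), and tabulates hub taxa (top decile by
# both degree and betweenness). The module carrying the Trichoderma OTUs is
# the one expected to couple positively to growth traits and enzymes and
# negatively to disease incidence.

suppressPackageStartupMessages(library(rhizonet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1

counts <- read_count_table("results/data/counts.tsv")
taxonomy <- read_taxonomy("results/data/taxonomy.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")
meta <- meta[match(colnames(counts), meta$sample_id), ]
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

design_cols <- c("sample_id", "crop", "treatment", "replicate")
trait_cols <- setdiff(names(meta)[vapply(meta, is.numeric, TRUE)], design_cols)
ra <- to_relative_abundance(counts)
focal_otus <- collapse_genus(counts, taxonomy, "Trichoderma")$members

mt_rows <- list(); hub_rows <- list()
for (g in split(meta$sample_id, paste(meta$crop, meta$treatment, sep = "_"))) {
  label <- paste(meta$crop[match(g[1], meta$sample_id)],
                 meta$treatment[match(g[1], meta$sample_id)], sep = "_")
  net <- suppressWarnings(group_network(counts, g, group = label))
  part <- detect_modules(net, seed = split_seed(seed, "modules"))
  write.table(part$membership,
              sprintf("results/tables/modules_%s.tsv", label),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!any(!is.na(part$membership$module))) next
  eg <- module_eigengenes(ra[net$nodes, g, drop = FALSE], part)
  vars <- meta[match(g, meta$sample_id), c("sample_id", trait_cols)]
  mt <- correlate_modules(eg, vars)
  mt_rows[[label]] <- cbind(group = label, mt$table)
  hb <- hub_nodes(net, part)
  hub_rows[[label]] <- cbind(group = label, hb[hb$degree > 0, ])

  focal_mods <- part$membership$module[part$membership$node %in% focal_otus]
  focal_mod <- if (all(is.na(focal_mods))) NA else
    names(which.max(table(focal_mods)))
  cat(sprintf("%s: %d labelled modules; focal genus in module %s\n",
              label, length(unique(na.omit(part$membership$module))),
              as.character(focal_mod)))
}
mt_all <- do.call(rbind, mt_rows)
write.table(mt_all, "results/tables/eigengene_trait.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, hub_rows), "results/tables/hubs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

top <- mt_all[order(mt_all$p), ]
top <- top[!is.na(top$r), ][1:min(8, sum(!is.na(top$r))), ]
cat("strongest module-trait couplings:\n")
for (i in seq_len(nrow(top)))
  cat(sprintf("  %s %s ~ %-20s r = %+.2f (p = %.3g, BH %.3g)\n",
              top$group[i], top$module[i], top$variable[i], top$r[i],
              top$p[i], top$p_adj[i]))
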