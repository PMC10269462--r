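#!/usr/bin/env Rscript
# Stage 5: the in-silico knockout.
#
# Asks whether the module containing the Trichoderma OTUs depends on them:
# remove the genus from the OTU table (or scale it down to the control's
# mean relative abundance), rebuild the coated network with identical
# parameters, re-detect modules, and measure the proportion of the original
# module's nodes recovered inside a single rebuilt module. A sham knockout
# of a genus outside the module is the specificity control.
#
# Runs twice: at the study's own scale (6 coated replicates, where
# correlation estimates are coarse) and in the estimation regime of the
# dedicated knockout scenario (50 coated samples).

suppressPackageStartupMessages(library(rhizonet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

run_ko <- function(counts, taxonomy, meta, samples, label) {
  ko <- tryCatch(suppressWarnings(
    knockout_experiment(counts, taxonomy, meta, "Trichoderma",
                        samples = samples, seed = split_seed(seed, "modules"))),
    error = function(e) e)
  if (inherits(ko, "error")) {
    cat(sprintf("%s: %s\n", label, conditionMessage(ko)))
    return(NULL)
  }
  gen <- split(taxonomy$taxon_id, taxonomy$genus)
  sham <- setdiff(sort(names(gen)[!vapply(gen, function(v)
    any(v %in% ko$target_module), TRUE)]), "Trichoderma")[1]
  ko_sham <- suppressWarnings(
    knockout_experiment(counts, taxonomy, meta, sham, samples = samples,
                        target = ko$target_module, modes = "remove",
                        seed = split_seed(seed, "modules")))
  rows <- rbind(
    data.frame(analysis = label, mode = "remove", genus = "Trichoderma",
               shared = ko$modes$remove$shared_proportion,
               verdict = ifelse(ko$modes$remove$persistent,
                                "persists", "dissolves"),
               shared_hubs = ko$modes$remove$shared_hub_count),
    data.frame(analysis = label, mode = "reduce", genus = "Trichoderma",
               shared = ko$modes$reduce$shared_proportion,
               verdict = ifelse(ko$modes$reduce$persistent,
                                "persists", "dissolves"),
               shared_hubs = ko$modes$reduce$shared_hub_count),
    data.frame(analysis = label, mode = "remove", genus = sham,
               shared = ko_sham$modes$remove$shared_proportion,
               verdict = ifelse(ko_sham$modes$remove$persistent,
                                "persists", "dissolves"),
               shared_hubs = ko_sham$modes$remove$shared_hub_count))
  for (i in seq_len(nrow(rows)))
    cat(sprintf("%s: %s %-10s shared %.2f -> %s\n", label, rows$mode[i],
                rows$genus[i], rows$shared[i], rows$verdict[i]))
  rows
}

# study scale
counts <- read_count_table("results/data/counts.tsv")
taxonomy <- read_taxonomy("results/data/taxonomy.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")
rows <- list()
for (crop in unique(meta$crop)) {
  smp <- meta$sample_id[meta$crop == crop & meta$treatment == "coated"]
  ctl <- meta$sample_id[meta$crop == crop & meta$treatment == "control"]
  rows[[crop]] <- run_ko(counts[, c(smp, ctl)], taxonomy, meta, smp,
                         paste0("study_", crop))
}

# estimation regime
com <- generate_counts(knockout_scenario(split_seed(seed, "knockout")))
smp <- com$metadata$sample_id[com$metadata$treatment == "coated"]
rows$regime <- run_ko(com$counts, com$taxonomy, com$metadata, smp,
                      "estimation_regime")

out <- do.call(rbind, rows)
write.table(out, "results/tables/knockout.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
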