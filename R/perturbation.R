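# In-silico knockout of a focal genus: remove its OTUs from the table, or
# scale them in coated samples down to the control's mean relative
# abundance, then rebuild the network, re-detect modules and ask whether
# the original focal module persists, measured by the proportion of its
# nodes recovered inside a single rebuilt module.

#' Remove a genus from the count table
#'
#' Drops all OTU rows annotated to the genus (case-insensitive); samples and
#' all other rows are untouched. An absent genus is a no-op with a warning.
#'
#' @param table Count matrix, taxa x samples.
#' @param taxonomy Taxonomy data frame.
#' @param genus Genus label.
#' @return The reduced count matrix.
#' @export
knockout_remove <- function(table, taxonomy, genus) {
  cg <- collapse_genus(table, taxonomy, genus)
  if (!length(cg$members)) return(table)
  table[setdiff(rownames(table), cg$members), , drop = FALSE]
}

#' Reduce a genus in coated samples to the control's mean relative abundance
#'
#' All member OTUs are scaled by one common factor (preserving within-genus
#' composition) chosen so that the genus's mean relative abundance across
#' coated samples equals its mean across control samples; counts are then
#' rounded to integers (zeros preserved). Control samples are never
#' modified. A genus absent from the control is zeroed in coated samples,
#' with a message.
#'
#' @param table Count matrix covering both treatments.
#' @param taxonomy Taxonomy data frame.
#' @param genus Genus label.
#' @param metadata Sample metadata with `sample_id` and the treatment column.
#' @param treatment_col Metadata column holding the treatment labels.
#' @param coated_label,control_label Treatment labels.
#' @return The adjusted count matrix (same dimensions).
#' @export
knockout_reduce <- function(table, taxonomy, genus, metadata,
                            treatment_col = "treatment",
                            coated_label = "coated",
                            control_label = "control") {
  cg <- collapse_genus(table, taxonomy, genus)
  if (!length(cg$members)) return(table)
  trt <- metadata[[treatment_col]][match(colnames(table),
                                         metadata$sample_id)]
  coated <- which(trt == coated_label)
  control <- which(trt == control_label)
  if (!length(coated) || !length(control))
    stop("both treatment groups must be present", call. = FALSE)
  ra <- to_relative_abundance(table)
  gra <- colSums(ra[cg$members, , drop = FALSE])
  m_coat <- mean(gra[coated]); m_ctrl <- mean(gra[control])
  if (m_coat == 0) return(table)
  factor <- m_ctrl / m_coat
  if (factor == 0)
    message("genus '", genus, "' absent from control; zeroing it in coated samples")
  out <- table
  out[cg$members, coated] <- as.integer(
    round(table[cg$members, coated, drop = FALSE] * factor))
  out
}

#' Match a target module against a rebuilt partition
#'
#' For every labelled rebuilt module, the proportion
#' `|target intersect module| / |target|` is computed, with the target first
#' restricted to nodes present in the rebuilt network; the maximising
#' module is returned (ties broken by smaller module id). Jaccard similarity
#' is reported alongside.
#'
#' @param target Character vector of target-module node ids.
#' @param partition `module_partition` of the rebuilt network.
#' @return List: `best_module`, `shared_proportion`, `jaccard`,
#'   `n_target_present`, `per_module` (data frame).
#' @export
match_modules <- function(target, partition) {
  stopifnot(length(target) > 0, inherits(partition, "module_partition"))
  mem <- partition$membership
  present <- intersect(target, mem$node)
  mods <- sort(unique(stats::na.omit(mem$module)))
  if (!length(mods) || !length(present)) {
    return(list(best_module = NA_integer_, shared_proportion = 0,
                jaccard = 0, n_target_present = length(present),
                per_module = data.frame(module = integer(0),
                                        shared = integer(0),
                                        proportion = numeric(0),
                                        jaccard = numeric(0))))
  }
  per <- do.call(rbind, lapply(mods, function(m) {
    nodes <- mem$node[!is.na(mem$module) & mem$module == m]
    sh <- length(intersect(present, nodes))
    data.frame(module = m, shared = sh,
               proportion = sh / length(present),
               jaccard = sh / length(union(present, nodes)))
  }))
  best <- per$module[order(-per$proportion, per$module)][1L]
  list(best_module = best,
       shared_proportion = per$proportion[per$module == best],
       jaccard = per$jaccard[per$module == best],
       n_target_present = length(present),
       per_module = per)
}

#' End-to-end knockout experiment
#'
#' Runs the full logic of the focal-genus dependence test on one group of
#' samples: (1) build the baseline network and partition and locate the
#' target module (the one containing most focal-genus OTUs, unless given);
#' (2) for each requested mode, perturb the count table (`remove` drops the
#' genus; `reduce` scales it down to control levels), rebuild the network on
#' the same samples with identical parameters and seed, re-detect modules,
#' and match the target module by shared-node proportion. In `remove` mode
#' the genus's own OTUs are excluded from the target before matching, so the
#' proportion asks whether the *companion* taxa stay together. Hub overlap
#' between the original target module and the best-matching rebuilt module
#' is reported alongside the verdict but not folded into it.
#'
#' @param table Full count matrix (all groups).
#' @param taxonomy Taxonomy data frame.
#' @param metadata Sample metadata (needed for `reduce`).
#' @param genus Genus to knock out.
#' @param samples Sample ids of the group whose network is analysed
#'   (typically the coated samples of one crop).
#' @param modes Subset of `c("remove", "reduce")`.
#' @param match_threshold Persistence verdict threshold on the shared-node
#'   proportion (default 0.5).
#' @param target Optional explicit target node set; default is the baseline
#'   module containing most focal-genus OTUs.
#' @param seed Seed forwarded to module detection (baseline and rebuilds).
#' @param min_module_size Passed to [detect_modules()].
#' @param top_fraction Passed to [hub_nodes()].
#' @param ... Network parameters passed to [group_network()].
#' @return Object of class `knockout_result`: `target_module` nodes,
#'   `baseline` (network + partition), and per-mode entries with the rebuilt
#'   network, partition, match, hub overlap and verdict.
#' @export
knockout_experiment <- function(table, taxonomy, metadata, genus,
                                samples, modes = c("remove", "reduce"),
                                match_threshold = 0.5, target = NULL,
                                seed = 1, min_module_size = 5,
                                top_fraction = 0.1, ...) {
  modes <- match.arg(modes, c("remove", "reduce"), several.ok = TRUE)
  net0 <- group_network(table, samples, ...)
  part0 <- detect_modules(net0, seed = seed, min_module_size = min_module_size)
  members_genus <- collapse_genus(table, taxonomy, genus)$members
  if (is.null(target)) {
    mem <- part0$membership
    counts_in <- table(mem$module[mem$node %in% members_genus])
    if (!length(counts_in))
      stop("focal genus '", genus,
           "' has no OTU in any labelled baseline module", call. = FALSE)
    target_id <- as.integer(names(which.max(counts_in)))
    target <- module_members(part0, target_id)
  }
  hubs0 <- hub_nodes(net0, part0, top_fraction = top_fraction)
  target_hubs <- hubs0$node[hubs0$hub & hubs0$node %in% target]

  results <- list()
  for (mode in modes) {
    tab2 <- switch(mode,
                   remove = knockout_remove(table, taxonomy, genus),
                   reduce = knockout_reduce(table, taxonomy, genus, metadata))
    net2 <- group_network(tab2, samples, ...)
    part2 <- detect_modules(net2, seed = seed,
                            min_module_size = min_module_size)
    tgt <- if (mode == "remove") setdiff(target, members_genus) else target
    m <- match_modules(tgt, part2)
    hubs2 <- hub_nodes(net2, part2, top_fraction = top_fraction)
    best_nodes <- if (is.na(m$best_module)) character(0) else
      module_members(part2, m$best_module)
    shared_hubs <- intersect(intersect(target_hubs, best_nodes),
                             hubs2$node[hubs2$hub])
    results[[mode]] <- list(
      mode = mode, network = net2, partition = part2, match = m,
      shared_proportion = m$shared_proportion,
      persistent = m$shared_proportion >= match_threshold,
      shared_hub_count = length(shared_hubs),
      shared_hubs = shared_hubs)
  }
  structure(list(genus = genus, target_module = target,
                 target_hubs = target_hubs,
                 baseline = list(network = net0, partition = part0),
                 match_threshold = match_threshold,
                 modes = results, seed = seed),
            class = "knockout_result")
}

#' @export
print.knockout_result <- function(x, ...) {
  cat(sprintf("knockout_result: genus %s, target module of %d nodes\n",
              x$genus, length(x$target_module)))
  for (r in x$modes)
    cat(sprintf("  %-6s shared %.2f -> %s (shared hubs: %d)\n", r$mode,
                r$shared_proportion,
                ifelse(r$persistent, "persists", "dissolves"),
                r$shared_hub_count))
  invisible(x)
}
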