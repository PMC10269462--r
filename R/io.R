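# Tabular I/O and the two normalisations used throughout: rarefaction
# (without-replacement subsampling to a common depth) and relative abundance.
# All tables are plain tab-separated text with explicit headers, taxa as rows.

#' Read / write an OTU count table
#'
#' Tab-separated text, first column `taxon_id`, remaining columns one per
#' sample. Cells must be non-negative integers; violations raise an error
#' naming the offending row and column. `write_count_table()` followed by
#' `read_count_table()` is the identity.
#'
#' @param path File path.
#' @return An integer matrix, taxa x samples, with dimnames.
#' @export
read_count_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("count table needs a taxon_id column plus at least one sample",
         call. = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate taxon ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw[-1L], is.numeric, TRUE))[1L]
    stop("non-numeric counts in column '", samples[bad], "'", call. = FALSE)
  }
  bad <- which(m < 0 | m != round(m) | !is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid count at taxon '%s', sample '%s': %s",
                 ids[bad[1L, 1L]], samples[bad[1L, 2L]],
                 m[bad[1L, , drop = FALSE]]), call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname read_count_table
#' @param table Integer matrix, taxa x samples.
#' @export
write_count_table <- function(table, path) {
  .assert_count_matrix(table)
  df <- data.frame(taxon_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a taxonomy table
#'
#' Tab-separated with columns `taxon_id`, `kingdom`, `phylum`, `class`,
#' `order`, `family`, `genus`; unassigned ranks may be empty or `NA`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(tx))
    stop("taxonomy table needs a 'taxon_id' column", call. = FALSE)
  if (anyDuplicated(tx$taxon_id))
    stop("duplicate taxon ids in taxonomy", call. = FALSE)
  tx
}

#' @rdname read_taxonomy
#' @param taxonomy Data frame as returned by [read_taxonomy()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Tab-separated with columns `sample_id`, `crop`, `treatment`, `replicate`
#' and any number of trait / enzyme columns. Missing trait values stay `NA`,
#' never silently zero.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md))
    stop("sample metadata needs a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  md
}

#' @rdname read_sample_metadata
#' @param metadata Data frame as returned by [read_sample_metadata()].
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rarefy a count table to a common depth
#'
#' Without-replacement (hypergeometric) subsampling of every sample to
#' `depth` reads, matching the convention of drawing a normalised number of
#' sequences from each sample. Zero counts can never become positive.
#'
#' @param table Count matrix, taxa x samples.
#' @param depth Target depth; defaults to the minimum sample total. Must not
#'   exceed any sample's total (shallow samples are listed in the error).
#' @param seed Seed making the subsampling reproducible.
#' @return An integer matrix of the same shape; every column sums to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1) {
  .assert_count_matrix(table)
  totals <- colSums(table)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  stopifnot(depth > 0)
  shallow <- colnames(table)[totals < depth]
  if (length(shallow))
    stop("rarefaction depth ", depth, " exceeds sample total for: ",
         paste(shallow, collapse = ", "), call. = FALSE)
  out <- with_seed(seed, t(vegan::rrarefy(t(table), depth)))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(table)
  out
}

#' Convert counts to relative abundances
#'
#' @param table Count matrix, taxa x samples; no sample may be all zero.
#' @return Numeric matrix with each column summing to 1.
#' @export
to_relative_abundance <- function(table) {
  .assert_count_matrix(table)
  totals <- colSums(table)
  zero <- colnames(table)[totals == 0]
  if (length(zero))
    stop("all-zero sample(s): ", paste(zero, collapse = ", "), call. = FALSE)
  sweep(table, 2L, totals, "/")
}

#' Collapse a genus to its member OTUs and summed counts
#'
#' Genus matching is case-insensitive and exact. An unknown genus returns an
#' empty member set with a warning rather than silent zeros.
#'
#' @param table Count matrix, taxa x samples.
#' @param taxonomy Taxonomy data frame with `taxon_id` and `genus` columns.
#' @param genus Genus label.
#' @return List with `members` (taxon ids) and `counts` (per-sample sums).
#' @export
collapse_genus <- function(table, taxonomy, genus) {
  .assert_count_matrix(table)
  stopifnot(all(c("taxon_id", "genus") %in% names(taxonomy)))
  hit <- !is.na(taxonomy$genus) &
    tolower(taxonomy$genus) == tolower(genus)
  members <- intersect(taxonomy$taxon_id[hit], rownames(table))
  if (!length(members)) {
    warning("genus '", genus, "' not found in taxonomy/table", call. = FALSE)
    return(list(members = character(0),
                counts = setNames(rep(NA_real_, ncol(table)),
                                  colnames(table))))
  }
  list(members = members,
       counts = colSums(table[members, , drop = FALSE]))
}
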