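# Alpha diversity (Shannon, Pielou, bias-corrected Chao1), Bray-Curtis beta
# diversity with PERMANOVA, and rank-based group comparisons with
# Benjamini-Hochberg correction. Standard index computations are delegated
# to vegan; the surfaces here add the study's conventions and validation.

#' Per-sample alpha diversity indices
#'
#' Shannon diversity in nats, Pielou evenness `H / ln(S_obs)` (defined as 1
#' for a single-taxon sample), and bias-corrected Chao1
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`/`F2` the singleton and
#' doubleton counts.
#'
#' @param table Count matrix, taxa x samples (integer counts; usually
#'   rarefied first).
#' @return Data frame with columns `sample_id`, `richness`, `shannon`,
#'   `pielou`, `chao1`.
#' @export
alpha_diversity <- function(table) {
  .assert_count_matrix(table)
  if (any(colSums(table) == 0))
    stop("all-zero sample(s) have undefined diversity", call. = FALSE)
  x <- t(table)                      # vegan wants samples as rows
  shannon <- vegan::diversity(x, index = "shannon")
  rich <- rowSums(x > 0)
  pielou <- ifelse(rich > 1, shannon / log(rich), 1)
  chao1 <- vegan::estimateR(x)["S.chao1", ]
  data.frame(sample_id = colnames(table), richness = as.numeric(rich),
             shannon = as.numeric(shannon), pielou = as.numeric(pielou),
             chao1 = as.numeric(chao1), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Two-group rank comparison
#'
#' Two-sided Wilcoxon rank-sum test (exact for small tie-free samples,
#' normal approximation with tie correction otherwise); a paired signed-rank
#' variant is available for genuinely paired designs. Completely tied input
#' yields p = 1 with a warning.
#'
#' @param values Numeric measurements.
#' @param groups Factor/character vector with exactly two levels.
#' @param paired Use the paired signed-rank test.
#' @return List with `statistic` and `p`.
#' @export
compare_groups <- function(values, groups, paired = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("compare_groups() needs exactly two groups", call. = FALSE)
  a <- values[groups == levels(groups)[1L]]
  b <- values[groups == levels(groups)[2L]]
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 observations per group", call. = FALSE)
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied; p set to 1", call. = FALSE)
    return(list(statistic = NA_real_, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Pairwise group tests for alpha diversity indices
#'
#' Wilcoxon rank-sum tests for every pair of groups and every index, with
#' one BH adjustment across the whole table.
#'
#' @param alpha Data frame from [alpha_diversity()].
#' @param groups Group label per sample (aligned with `alpha$sample_id`).
#' @param indices Index columns to test.
#' @return Data frame: index, group pair, statistic, p, p_adj.
#' @export
alpha_group_tests <- function(alpha, groups,
                              indices = c("shannon", "pielou", "chao1")) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(alpha))
  lv <- levels(groups)
  rows <- list()
  for (i in seq_along(lv)) for (j in seq_len(i - 1L)) {
    sel <- groups %in% c(lv[i], lv[j])
    for (ix in indices) {
      ct <- compare_groups(alpha[[ix]][sel], droplevels(groups[sel]))
      rows[[length(rows) + 1L]] <- data.frame(
        index = ix, group1 = lv[j], group2 = lv[i],
        statistic = ct$statistic, p = ct$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_bh(out$p)
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = 1 - 2 sum(min(a_i, b_i)) / sum(a_i + b_i)` between sample
#' columns; symmetric with zero diagonal, values in \[0, 1\] for
#' relative-abundance input.
#'
#' @param table Relative-abundance (or count) matrix, taxa x samples.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(table) {
  if (ncol(table) < 2L)
    stop("need at least 2 samples", call. = FALSE)
  vegan::vegdist(t(table), method = "bray")
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance (Adonis): pseudo-F from
#' the among/within partition of the distance matrix, with permutation
#' p-value `(1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @param dist A `dist` object (e.g. from [bray_curtis()]).
#' @param groups Group label per sample; every group needs >= 2 samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @return List of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `n_perm`, `seed`, `df`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("singleton group(s): ",
         paste(names(which(table(groups) < 2L)), collapse = ", "),
         call. = FALSE)
  df <- data.frame(group = groups)
  fit <- with_seed(seed,
                   vegan::adonis2(dist ~ group, data = df,
                                  permutations = n_perm))
  structure(list(pseudo_F = fit$F[1L], R2 = fit$R2[1L],
                 p = fit$`Pr(>F)`[1L], n_perm = n_perm, seed = seed,
                 df = c(between = fit$Df[1L],
                        residual = fit$Df[nrow(fit) - 1L])),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}
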