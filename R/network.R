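# Signed Spearman co-occurrence networks, their topology, module detection,
# and natural-connectivity robustness under random node removal.
#
# Edge rule: |rho| strictly greater than the rho threshold AND p strictly
# below the p threshold (defaults 0.8 / 0.05, raw p). Natural connectivity
# is the log of the average eigenvalue exponential of the binary adjacency
# matrix of the current (sub)graph.

#' Prevalence / abundance filter preceding network construction
#'
#' Rank correlations on near-constant vectors at small n are meaningless,
#' so taxa must be present in at least `min_prevalence` samples of the group
#' and reach a minimum mean relative abundance.
#'
#' @param table Count matrix (taxa x samples) for one group.
#' @param min_prevalence Minimum number of samples with a non-zero count.
#' @param min_mean_relabund Minimum mean relative abundance.
#' @return Character vector of surviving taxon ids.
#' @export
filter_taxa <- function(table, min_prevalence = 3, min_mean_relabund = 1e-4) {
  .assert_count_matrix(table)
  ra <- to_relative_abundance(table)
  keep <- rowSums(table > 0) >= min_prevalence &
    rowMeans(ra) >= min_mean_relabund
  rownames(table)[keep]
}

# Exact null distribution of the Spearman D statistic (sum of squared rank
# differences) for tie-free samples of size n, by full enumeration of the
# n! rank permutations. Cached per n; only used for n <= 9.
.perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perm_matrix(n - 1L)
  f <- nrow(sub)
  out <- matrix(0L, f * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * f + seq_len(f)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], f, n - 1L)
  }
  out
}

.spearman_null_cdf <- function(n) {
  key <- paste0("spearman_null_", n)
  hit <- get0(key, envir = .rhizonet_cache)
  if (!is.null(hit)) return(hit)
  pm <- .perm_matrix(n)
  d2 <- rowSums((pm - matrix(seq_len(n), nrow(pm), n, byrow = TRUE))^2)
  dmax <- n * (n^2 - 1) / 3
  counts <- tabulate(d2 + 1L, nbins = dmax + 1L)
  cdf <- cumsum(counts) / nrow(pm)           # P(D <= d), d = 0..dmax
  assign(key, cdf, envir = .rhizonet_cache)
  cdf
}

#' Spearman correlation of two vectors with its two-sided p-value
#'
#' Tie-corrected rho (Pearson correlation of average ranks). The p-value is
#' exact (full enumeration of rank permutations) for tie-free input with
#' `n <= exact_max_n`, otherwise the t approximation with `n - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param exact_max_n Largest n for which the exact null is enumerated.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y, exact_max_n = 9) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  tied <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  p <- if (!tied && n <= exact_max_n) {
    cdf <- .spearman_null_cdf(n)
    d2 <- round(sum((rx - ry)^2))
    lo <- cdf[d2 + 1L]                              # P(D <= d2) -> rho >= obs
    hi <- 1 - if (d2 == 0) 0 else cdf[d2]           # P(D >= d2) -> rho <= obs
    min(1, 2 * min(lo, hi))
  } else {
    r <- min(1 - 1e-12, abs(rho))
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-tt, n - 2)
  }
  list(rho = rho, p = p)
}

#' Pairwise Spearman correlation and p-value matrices for one group
#'
#' Tie-corrected rho for every taxon pair across the group's samples, with
#' two-sided p-values (exact by enumeration for tie-free pairs when
#' `n <= exact_max_n`, t approximation otherwise). Constant taxa yield `NA`
#' rows/columns and a warning.
#'
#' @param rel_abund Relative-abundance (or count) matrix, taxa x samples,
#'   restricted to the samples of one group (>= 4; a warning is issued
#'   below 6).
#' @param exact_max_n See [spearman_cor()].
#' @return List with symmetric matrices `rho` and `p` (unit / zero
#'   diagonal), and `n` samples.
#' @export
spearman_matrix <- function(rel_abund, exact_max_n = 9) {
  n <- ncol(rel_abund)
  if (n < 4L) stop("need at least 4 samples for rank correlation", call. = FALSE)
  if (n < 6L) warning("fewer than 6 samples; correlations will be coarse",
                      call. = FALSE)
  R <- apply(t(rel_abund), 2L, rank)            # samples x taxa, average ranks
  sds <- apply(R, 2L, stats::sd)
  const <- sds == 0
  if (any(const))
    warning(sum(const), " constant taxa excluded from correlation",
            call. = FALSE)
  rho <- suppressWarnings(stats::cor(R))
  rho[const, ] <- NA; rho[, const] <- NA
  diag(rho) <- 1

  # t approximation everywhere, then overwrite exactly computable pairs
  r <- abs(rho)
  r[!is.na(r) & r > 1 - 1e-12] <- 1 - 1e-12
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-tt, n - 2)
  if (n <= exact_max_n) {
    tiefree <- !const & apply(R, 2L, anyDuplicated) == 0L
    ix <- which(tiefree)
    if (length(ix) >= 2L) {
      cdf <- .spearman_null_cdf(n)
      Rt <- R[, ix, drop = FALSE]
      # D = sum((r_x - r_y)^2) for all tie-free pairs at once
      cross <- crossprod(Rt)
      ss <- sum(seq_len(n)^2)
      D <- round(outer(rep(ss, length(ix)), rep(ss, length(ix)), "+") - 2 * cross)
      lo <- matrix(cdf[D + 1L], nrow(D))
      hi <- 1 - ifelse(D == 0, 0, matrix(cdf[pmax(D, 1L)], nrow(D)))
      pe <- pmin(1, 2 * pmin(lo, hi))
      p[ix, ix] <- pe
    }
  }
  diag(p) <- 0
  p[is.na(rho)] <- NA
  dimnames(rho) <- dimnames(p) <- list(rownames(rel_abund), rownames(rel_abund))
  list(rho = rho, p = p, n = n)
}

#' Build a signed co-occurrence network from correlation matrices
#'
#' An edge joins two taxa iff `|rho| > rho_threshold` (strict) and
#' `p < p_threshold` (strict). P-values are raw by default; `p_adjust = TRUE`
#' applies BH across all pairs first. All filtered taxa remain as nodes even
#' if edgeless.
#'
#' @param rho,p Symmetric matrices from [spearman_matrix()].
#' @param rho_threshold Correlation magnitude threshold (default 0.8).
#' @param p_threshold Significance threshold (default 0.05).
#' @param p_adjust Apply BH adjustment to the pairwise p-values first.
#' @param group Optional group label carried by the network.
#' @return An object of class `coocc_network`: `graph` (igraph), `nodes`,
#'   `edges` (data frame: from, to, rho, p, sign), `params`, `group`.
#' @export
build_network <- function(rho, p, rho_threshold = 0.8, p_threshold = 0.05,
                          p_adjust = FALSE, group = NA_character_) {
  stopifnot(identical(dim(rho), dim(p)))
  nodes <- rownames(rho)
  ut <- upper.tri(rho)
  pv <- p
  if (p_adjust) {
    adj <- stats::p.adjust(p[ut], method = "BH")
    pv[ut] <- adj
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  }
  sel <- ut & !is.na(rho) & !is.na(pv) &
    abs(rho) > rho_threshold & pv < p_threshold
  ij <- which(sel, arr.ind = TRUE)
  edges <- data.frame(from = nodes[ij[, 1L]], to = nodes[ij[, 2L]],
                      rho = rho[sel], p = pv[sel],
                      sign = ifelse(rho[sel] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    warning("network has no edges under the given thresholds", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, nodes = nodes, edges = edges,
                 params = list(rho_threshold = rho_threshold,
                               p_threshold = p_threshold,
                               p_adjust = p_adjust),
                 group = group),
            class = "coocc_network")
}

#' @export
print.coocc_network <- function(x, ...) {
  neg <- if (nrow(x$edges)) mean(x$edges$sign == "negative") else NA
  cat(sprintf("coocc_network [%s]: %d nodes, %d edges (%.1f%% negative), |rho| > %g, p < %g\n",
              ifelse(is.na(x$group), "ungrouped", x$group),
              length(x$nodes), nrow(x$edges),
              100 * ifelse(is.na(neg), 0, neg),
              x$params$rho_threshold, x$params$p_threshold))
  invisible(x)
}

#' One-call network construction for a group of samples
#'
#' Filter taxa, convert to relative abundance, compute the Spearman
#' matrices and apply the edge rule.
#'
#' @param table Count matrix, taxa x samples.
#' @param samples Sample ids of the group (default: all columns).
#' @param min_prevalence,min_mean_relabund See [filter_taxa()].
#' @param ... Passed to [build_network()].
#' @return A `coocc_network`.
#' @export
group_network <- function(table, samples = colnames(table),
                          min_prevalence = 3, min_mean_relabund = 1e-4, ...) {
  sub <- table[, samples, drop = FALSE]
  keep <- filter_taxa(sub, min_prevalence, min_mean_relabund)
  if (length(keep) < 2L)
    stop("fewer than 2 taxa survive the prevalence/abundance filter",
         call. = FALSE)
  ra <- to_relative_abundance(sub[keep, , drop = FALSE])
  sm <- spearman_matrix(ra)
  net <- build_network(sm$rho, sm$p, ...)
  net$params$min_prevalence <- min_prevalence
  net$params$min_mean_relabund <- min_mean_relabund
  net$params$n_samples <- ncol(sub)
  net
}

#' Proportion of negative edges
#'
#' @param net A `coocc_network`.
#' @return Fraction of edges with negative rho, or `NA` (with a warning)
#'   for an edgeless network.
#' @export
negative_edge_ratio <- function(net) {
  stopifnot(inherits(net, "coocc_network"))
  if (nrow(net$edges) == 0L) {
    warning("no edges; negative-edge ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(net$edges$sign == "negative")
}

#' Module detection on the unsigned edge set
#'
#' Community detection with `|rho|` as edge weight. The default is the
#' map-equation (Infomap) algorithm, which keeps a marginally-sampled dense
#' module intact where plain modularity maximisation tends to fragment it;
#' greedy modularity agglomeration (`"fast_greedy"`) is available for
#' comparison. Modules smaller than `min_module_size` are left unlabelled
#' (`NA`); remaining modules are renumbered by decreasing size (ties by
#' smallest member id) so that ids are stable under a fixed seed, but module
#' identity should always be resolved by content, never by ordinal number.
#'
#' @param net A `coocc_network`.
#' @param seed Seed controlling the (stochastic) community search.
#' @param min_module_size Smallest labelled module (default 5).
#' @param algorithm `"infomap"` (default) or `"fast_greedy"`.
#' @return Object of class `module_partition`: `membership` (data frame
#'   node/module), `modularity` (of the found partition),
#'   `seed`, `min_module_size`, `algorithm`.
#' @export
detect_modules <- function(net, seed = 1, min_module_size = 5,
                           algorithm = c("infomap", "fast_greedy")) {
  stopifnot(inherits(net, "coocc_network"))
  algorithm <- match.arg(algorithm)
  g <- net$graph
  if (igraph::ecount(g) == 0L) {
    mem <- rep(NA_integer_, length(net$nodes))
    q <- NA_real_
  } else {
    w <- abs(igraph::E(g)$rho)
    cm <- with_seed(seed, switch(algorithm,
      infomap = igraph::cluster_infomap(g, e.weights = w),
      fast_greedy = igraph::cluster_fast_greedy(g, weights = w)))
    mem <- igraph::membership(cm)[net$nodes]
    q <- igraph::modularity(g, igraph::membership(cm), weights = w)
    sizes <- table(mem)
    small <- names(sizes)[sizes < min_module_size]
    mem[as.character(mem) %in% small] <- NA
    lab <- sort(unique(stats::na.omit(mem)))
    if (length(lab)) {
      key <- vapply(lab, function(l) {
        nm <- sort(net$nodes[!is.na(mem) & mem == l])
        sprintf("%09d_%s", 1e8 - sum(mem == l, na.rm = TRUE), nm[1L])
      }, "")
      newid <- match(lab, lab[order(key)])
      mem <- newid[match(mem, lab)]
    }
  }
  structure(list(membership = data.frame(node = net$nodes,
                                         module = as.integer(mem),
                                         stringsAsFactors = FALSE),
                 modularity = q, seed = seed,
                 min_module_size = min_module_size,
                 algorithm = algorithm),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tb <- table(x$membership$module, useNA = "ifany")
  cat(sprintf("module_partition: %d labelled module(s), modularity %.3f\n",
              sum(!is.na(names(tb))), x$modularity))
  invisible(x)
}

#' Module members from a partition
#'
#' @param partition A `module_partition`.
#' @param module Module id.
#' @return Character vector of node ids.
#' @export
module_members <- function(partition, module) {
  m <- partition$membership
  m$node[!is.na(m$module) & m$module == module]
}

# Adjacency matrix (binary by default) from the accepted input types.
.adjacency <- function(x, weighted = FALSE) {
  if (inherits(x, "coocc_network")) x <- x$graph
  if (igraph::is_igraph(x)) {
    A <- as.matrix(igraph::as_adjacency_matrix(
      x, attr = if (weighted && "rho" %in% igraph::edge_attr_names(x)) "rho"
      else NULL, sparse = FALSE))
    if (weighted) A <- abs(A)
  } else {
    A <- as.matrix(x)
    stopifnot(nrow(A) == ncol(A))
    if (!weighted) A <- (A != 0) * 1
    A <- abs(A)
  }
  diag(A) <- 0
  if (!weighted) A <- (A > 0) * 1
  (A + t(A)) / 2                       # enforce exact symmetry
}

#' Natural connectivity of a graph
#'
#' `ln( mean_i exp(lambda_i) )` over the eigenvalues of the (binary, by
#' convention) adjacency matrix — the log average closed-walk weight, a
#' spectral measure of route redundancy. Computed with an internal
#' log-sum-exp so large graphs do not overflow. An empty graph scores 0.
#'
#' @param x A `coocc_network`, igraph graph, or adjacency matrix.
#' @param weighted Use `|rho|`-weighted adjacency instead of binary.
#' @return A scalar.
#' @export
natural_connectivity <- function(x, weighted = FALSE) {
  A <- .adjacency(x, weighted)
  N <- nrow(A)
  if (N == 0L) stop("graph has no nodes", call. = FALSE)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  m <- max(ev)
  m + log(mean(exp(ev - m)))
}

#' Natural-connectivity robustness curve under random node removal
#'
#' For each removal fraction f, `round(f * N)` nodes (half-away-from-zero
#' rounding, for bit-reproducible curves) are removed uniformly at random
#' and natural connectivity is recomputed on the induced subgraph; the mean
#' and sd over `n_reps` removals are reported. Fraction 0 reproduces the
#' intact value exactly.
#'
#' @param net A `coocc_network` (or igraph/adjacency input).
#' @param fractions Removal fractions in \[0, 1); none may remove all nodes.
#' @param n_reps Random removals per fraction.
#' @param seed Seed.
#' @param weighted See [natural_connectivity()].
#' @return Object of class `robustness_curve`: data frame `curve`
#'   (fraction, n_removed, mean, sd), `intact`, `n_reps`, `seed`.
#' @export
robustness_curve <- function(net, fractions = c(0.01, seq(0.05, 0.60, 0.05)),
                             n_reps = 30, seed = 1, weighted = FALSE) {
  A <- .adjacency(net, weighted)
  N <- nrow(A)
  stopifnot(all(fractions >= 0), all(fractions < 1))
  k <- floor(fractions * N + 0.5)
  if (any(k >= N)) stop("a fraction would remove every node", call. = FALSE)
  intact <- natural_connectivity(A, weighted = FALSE)
  curve <- with_seed(seed, {
    do.call(rbind, lapply(seq_along(fractions), function(i) {
      if (k[i] == 0L)
        return(data.frame(fraction = fractions[i], n_removed = 0L,
                          mean = intact, sd = 0))
      vals <- vapply(seq_len(n_reps), function(r) {
        keep <- sample.int(N, N - k[i])
        natural_connectivity(A[keep, keep, drop = FALSE])
      }, 0)
      data.frame(fraction = fractions[i], n_removed = k[i],
                 mean = mean(vals), sd = stats::sd(vals))
    }))
  })
  structure(list(curve = curve, intact = intact, n_reps = n_reps,
                 seed = seed), class = "robustness_curve")
}

#' Area under a robustness curve
#'
#' Trapezoidal area of mean natural connectivity over the removal-fraction
#' grid; a single-number stability summary for group comparisons.
#'
#' @param rc A `robustness_curve`.
#' @return A scalar.
#' @export
robustness_auc <- function(rc) {
  stopifnot(inherits(rc, "robustness_curve"))
  cv <- rc$curve[order(rc$curve$fraction), ]
  x <- cv$fraction; y <- cv$mean
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat(sprintf("robustness_curve: intact natural connectivity %.4f, %d fractions x %d reps\n",
              x$intact, nrow(x$curve), x$n_reps))
  invisible(x)
}

#' Export network edges as a tab-separated edge list
#'
#' @param net A `coocc_network`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "coocc_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
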