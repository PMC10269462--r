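# Module eigengenes (first principal component of standardised member
# abundance profiles), eigengene-trait/enzyme correlations, and hub
# identification by joint degree and betweenness.

#' Module eigengene
#'
#' Each member taxon's abundance profile is log-transformed (with a
#' per-taxon pseudocount of half that taxon's smallest positive value, so
#' zeros stay finite)
#' and standardised (zero mean, unit variance across samples); the
#' eigengene is the first principal component score vector of the resulting
#' samples x members matrix — a one-number-per-sample summary of module
#' activity. The log transform linearises the multiplicative mean-abundance
#' relation of compositional data (without it, PC scores are dominated by
#' the exponential upper tail) and makes the eigengene exactly invariant to
#' rescaling any taxon by a positive constant. Its sign is oriented so that
#' it correlates positively with the module's mean standardised abundance.
#' Constant member profiles are dropped with a warning; a module collapsing
#' below 2 usable members is an error.
#'
#' @param rel_abund Relative-abundance matrix, taxa x samples.
#' @param members Taxon ids of the module (>= 2).
#' @param module Optional module id carried in the result.
#' @param transform `"log"` (default) or `"none"`.
#' @return Object of class `eigengene`: `scores` (named per-sample vector,
#'   zero mean), `var_explained` in (0, 1\], `module`, `flipped`.
#' @export
module_eigengene <- function(rel_abund, members, module = NA,
                             transform = c("log", "none")) {
  transform <- match.arg(transform)
  members <- intersect(members, rownames(rel_abund))
  if (length(members) < 2L)
    stop("module has fewer than 2 members present in the table", call. = FALSE)
  if (ncol(rel_abund) < 3L)
    stop("need at least 3 samples", call. = FALSE)
  X <- t(rel_abund[members, , drop = FALSE])       # samples x members
  if (transform == "log") {
    X <- apply(X, 2L, function(col) {
      pos <- col[col > 0]
      pc <- if (length(pos)) min(pos) / 2 else 1
      log(col + pc)
    })
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant member profile(s) dropped", call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2L)
      stop("module collapsed below 2 non-constant members", call. = FALSE)
  }
  Xs <- scale(X)
  sv <- svd(Xs)
  scores <- sv$u[, 1L] * sv$d[1L]
  var_explained <- sv$d[1L]^2 / sum(sv$d^2)
  flipped <- FALSE
  mstd <- rowMeans(Xs)
  if (stats::sd(mstd) > 0 && stats::cor(scores, mstd) < 0) {
    scores <- -scores
    flipped <- TRUE
  }
  structure(list(scores = stats::setNames(as.numeric(scores),
                                          colnames(rel_abund)),
                 var_explained = var_explained, module = module,
                 flipped = flipped, n_members = ncol(Xs)),
            class = "eigengene")
}

#' @export
print.eigengene <- function(x, ...) {
  cat(sprintf("eigengene (module %s): %d members, %.1f%% variance explained\n",
              as.character(x$module), x$n_members, 100 * x$var_explained))
  invisible(x)
}

#' Eigengenes for every labelled module of a partition
#'
#' @param rel_abund Relative-abundance matrix, taxa x samples.
#' @param partition A `module_partition` from [detect_modules()].
#' @return Named list of `eigengene` objects (one per labelled module).
#' @export
module_eigengenes <- function(rel_abund, partition) {
  stopifnot(inherits(partition, "module_partition"))
  mods <- sort(unique(stats::na.omit(partition$membership$module)))
  out <- lapply(mods, function(m)
    module_eigengene(rel_abund, module_members(partition, m), module = m))
  stats::setNames(out, paste0("module_", mods))
}

#' Correlate module eigengenes with trait / enzyme variables
#'
#' Pearson (default) or Spearman correlation of every eigengene with every
#' variable, two-sided p-values, pairwise deletion of missing trait values,
#' and one BH adjustment across the whole module x variable matrix.
#'
#' @param eigengenes List of `eigengene` objects (see [module_eigengenes()])
#'   or a samples x modules score matrix.
#' @param variables Data frame of per-sample variables (rows aligned with
#'   the eigengene samples; a `sample_id` column, if present, is used to
#'   align).
#' @param method `"pearson"` or `"spearman"`.
#' @return Object of class `module_trait_cor`: long data frame `table`
#'   (module, variable, r, n, p, p_adj) plus matrices `r`, `p`, `p_adj`.
#' @export
correlate_modules <- function(eigengenes, variables,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.list(eigengenes) && !is.data.frame(eigengenes) &&
      all(vapply(eigengenes, inherits, TRUE, "eigengene"))) {
    E <- do.call(cbind, lapply(eigengenes, `[[`, "scores"))
    colnames(E) <- names(eigengenes)
  } else {
    E <- as.matrix(eigengenes)
  }
  if ("sample_id" %in% names(variables)) {
    rownames(variables) <- variables$sample_id
    if (!is.null(rownames(E)))
      variables <- variables[rownames(E), , drop = FALSE]
    variables$sample_id <- NULL
  }
  num <- vapply(variables, is.numeric, TRUE)
  variables <- variables[, num, drop = FALSE]
  if (!ncol(variables)) stop("no numeric variables to correlate", call. = FALSE)
  stopifnot(nrow(variables) == nrow(E))

  rows <- list()
  for (m in colnames(E)) for (v in colnames(variables)) {
    x <- E[, m]; y <- variables[[v]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(y[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, variable = v, r = NA_real_, n = sum(ok), p = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = method, exact = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      module = m, variable = v, r = unname(ct$estimate), n = sum(ok),
      p = ct$p.value, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- adjust_bh(tab$p)
  mk <- function(col) {
    M <- matrix(NA_real_, ncol(E), ncol(variables),
                dimnames = list(colnames(E), colnames(variables)))
    M[cbind(tab$module, tab$variable)] <- tab[[col]]
    M
  }
  structure(list(table = tab, r = mk("r"), p = mk("p"), p_adj = mk("p_adj"),
                 method = method),
            class = "module_trait_cor")
}

#' @export
print.module_trait_cor <- function(x, ...) {
  cat(sprintf("module_trait_cor (%s): %d modules x %d variables\n",
              x$method, nrow(x$r), ncol(x$r)))
  invisible(x)
}

#' Hub taxa by joint degree and betweenness
#'
#' Betweenness is shortest-path betweenness on the unweighted graph,
#' normalised to \[0, 1\]. A node is flagged as a hub when it lies in the
#' top `top_fraction` of the whole network by *both* degree and betweenness;
#' cutoffs are the k-th largest values (k = `ceiling(top_fraction * N)`) and
#' ties keep all tied nodes.
#'
#' @param net A `coocc_network`.
#' @param partition Optional `module_partition` to annotate nodes.
#' @param top_fraction Top fraction defining "high" (default 0.1).
#' @return Data frame: node, module, degree, betweenness, hub.
#' @export
hub_nodes <- function(net, partition = NULL, top_fraction = 0.1) {
  stopifnot(inherits(net, "coocc_network"))
  g <- net$graph
  N <- length(net$nodes)
  deg <- igraph::degree(g)[net$nodes]
  btw <- if (igraph::ecount(g) > 0L && N > 2L)
    igraph::betweenness(g, directed = FALSE, weights = NA,
                        normalized = TRUE)[net$nodes]
  else stats::setNames(rep(0, N), net$nodes)
  k <- max(1L, ceiling(top_fraction * N))
  dcut <- sort(deg, decreasing = TRUE)[k]
  bcut <- sort(btw, decreasing = TRUE)[k]
  hub <- deg >= dcut & btw >= bcut & deg > 0
  mod <- if (is.null(partition)) rep(NA_integer_, N) else
    partition$membership$module[match(net$nodes, partition$membership$node)]
  data.frame(node = net$nodes, module = mod, degree = as.numeric(deg),
             betweenness = as.numeric(btw), hub = unname(hub),
             row.names = NULL, stringsAsFactors = FALSE)
}
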