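# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (enumeration, matrix exponentials,
# definition-level formulas) and must stay independent of the package's own
# computation paths.

# Natural connectivity via the matrix exponential trace.
nc_expm_oracle <- function(A) {
  N <- nrow(A)
  log(sum(diag(as.matrix(Matrix::expm(A)))) / N)
}

# All permutations of 1..n, built iteratively by insertion (distinct from
# the recursive block construction inside the package).
perms_oracle <- function(n) {
  out <- list(1L)
  for (k in 2:n) {
    nxt <- list()
    for (p in out) for (pos in 0:(k - 1L)) {
      nxt[[length(nxt) + 1L]] <- append(p, k, after = pos)
    }
    out <- nxt
  }
  out
}

# Exact two-sided Spearman p-value by enumeration (tie-free input).
spearman_p_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  d2_obs <- sum((rx - ry)^2)
  d2_all <- vapply(perms_oracle(n), function(p) sum((seq_len(n) - p)^2), 0)
  lo <- mean(d2_all <= d2_obs)   # at least as positive
  hi <- mean(d2_all >= d2_obs)   # at least as negative
  min(1, 2 * min(lo, hi))
}

# Normalised betweenness by exhaustive simple-path enumeration (n <= 8).
betweenness_oracle <- function(A) {
  n <- nrow(A)
  paths_between <- function(s, t) {
    res <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { res[[length(res) + 1L]] <<- path; return(invisible()) }
      for (w in which(A[v, ] > 0)) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    res
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (!length(ps)) next
    lens <- lengths(ps)
    shortest <- ps[lens == min(lens)]
    sigma <- length(shortest)
    for (p in shortest) {
      inner <- setdiff(p, c(s, t))
      btw[inner] <- btw[inner] + 1 / sigma
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# PERMANOVA pseudo-F from the Gower-centred distance matrix partition.
permanova_F_oracle <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.factor(groups)
  a <- nlevels(groups)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  X <- stats::model.matrix(~ groups)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ssa <- sum(diag(H %*% G %*% H))
  ssw <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
  (ssa / (a - 1)) / (ssw / (n - a))
}

# Random symmetric binary adjacency matrix without self-loops.
random_adjacency <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# Tiny scenarios used by several unit-test files.
tiny_scenario <- function(seed = 1, ...) {
  synthetic_scenario(
    n_taxa = 30, n_samples_per_group = 5,
    groups = data.frame(crop = "maize", treatment = c("coated", "control")),
    modules = list(module_spec(size = 6, loading = 0.9)),
    sequencing_depth_mean = 5000, seed = seed, ...)
}
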