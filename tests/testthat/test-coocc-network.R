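# Spearman matrices, the edge rule, module detection, natural connectivity
# and robustness curves.

test_that("Spearman rho reproduces the rank-difference formula", {
  expect_equal(spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho, 0.8)
  x <- rnorm(10)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_equal(spearman_cor(x, rev(sort(x)))$rho,
               cor(x, rev(sort(x)), method = "spearman"))
})

test_that("exact small-n p-values match an independent enumeration", {
  set.seed(3)
  for (n in c(5, 6, 7)) {
    for (i in 1:5) {
      x <- rnorm(n); y <- rnorm(n)
      got <- spearman_cor(x, y)
      expect_equal(got$p, spearman_p_oracle(x, y), tolerance = 1e-12)
      ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
      expect_equal(got$p, ct$p.value, tolerance = 1e-9)
    }
  }
})

test_that("tied input falls back to the tie-corrected t approximation", {
  x <- c(1, 1, 2, 3, 4, 5); y <- c(2, 1, 1, 3, 5, 4)
  got <- spearman_cor(x, y)
  expect_equal(got$rho, cor(x, y, method = "spearman"))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(got$p, ct$p.value, tolerance = 1e-9)
})

test_that("spearman_matrix is symmetric, excludes constant taxa, matches pairwise calls", {
  set.seed(4)
  m <- matrix(rpois(8 * 50, 20), 50, 8,
              dimnames = list(paste0("t", 1:50), paste0("s", 1:8)))
  m["t3", ] <- 7L                                # constant taxon
  expect_warning(sm <- spearman_matrix(m), "constant")
  expect_true(all(is.na(sm$rho["t3", -3])))
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 50))
  pairwise <- spearman_cor(m["t1", ], m["t2", ])
  expect_equal(sm$rho["t1", "t2"], pairwise$rho)
  expect_equal(sm$p["t1", "t2"], pairwise$p)
})

test_that("the edge rule is strict at both thresholds and carries signs", {
  rho <- diag(3); p <- matrix(0, 3, 3)
  dimnames(rho) <- dimnames(p) <- list(letters[1:3], letters[1:3])
  rho["a", "b"] <- rho["b", "a"] <- 0.85; p["a", "b"] <- p["b", "a"] <- 0.01
  rho["a", "c"] <- rho["c", "a"] <- 0.80; p["a", "c"] <- p["c", "a"] <- 0.001
  rho["b", "c"] <- rho["c", "b"] <- -0.9; p["b", "c"] <- p["c", "b"] <- 0.2
  net <- suppressWarnings(build_network(rho, p))
  expect_equal(nrow(net$edges), 1L)              # only the (a,b) pair
  expect_equal(net$edges$sign, "positive")
  rho["b", "c"] <- rho["c", "b"] <- -0.9; p["b", "c"] <- p["c", "b"] <- 0.01
  net2 <- build_network(rho, p)
  expect_setequal(net2$edges$sign, c("positive", "negative"))
  expect_equal(negative_edge_ratio(net2), 0.5)
})

test_that("negative edge ratio handles the documented cases", {
  rho <- diag(5); p <- matrix(1, 5, 5); diag(p) <- 0
  dimnames(rho) <- dimnames(p) <- list(letters[1:5], letters[1:5])
  set_edge <- function(i, j, r) {
    rho[i, j] <<- rho[j, i] <<- r; p[i, j] <<- p[j, i] <<- 0.001
  }
  set_edge(1, 2, 0.9); set_edge(1, 3, 0.95); set_edge(2, 3, 0.85)
  set_edge(4, 5, -0.9)
  net <- build_network(rho, p)
  expect_equal(negative_edge_ratio(net), 0.25)
  r2 <- diag(2); p2 <- matrix(1, 2, 2)
  dimnames(r2) <- dimnames(p2) <- list(c("a", "b"), c("a", "b"))
  empty <- suppressWarnings(build_network(r2, p2))
  expect_warning(r <- negative_edge_ratio(empty), "undefined")
  expect_true(is.na(r))
})

test_that("network construction is invariant to taxon row order", {
  com <- generate_counts(tiny_scenario(12))
  smp <- com$metadata$sample_id[com$metadata$treatment == "coated"]
  n1 <- suppressWarnings(group_network(com$counts, smp))
  perm <- sample(nrow(com$counts))
  n2 <- suppressWarnings(group_network(com$counts[perm, ], smp))
  key <- function(net) {
    e <- net$edges
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), round(e$rho, 12)))
  }
  expect_identical(key(n1), key(n2))
})

test_that("module detection separates disconnected cliques and labels by size", {
  rho <- diag(12); p <- matrix(1, 12, 12); diag(p) <- 0
  ids <- paste0("n", 1:12)
  dimnames(rho) <- dimnames(p) <- list(ids, ids)
  for (i in 1:6) for (j in 1:6) if (i < j) {
    rho[i, j] <- rho[j, i] <- 0.9; p[i, j] <- p[j, i] <- 1e-4
  }
  for (i in 7:12) for (j in 7:12) if (i < j) {
    rho[i, j] <- rho[j, i] <- 0.85; p[i, j] <- p[j, i] <- 1e-4
  }
  net <- build_network(rho, p)
  part <- detect_modules(net, seed = 1)
  mem <- part$membership$module
  expect_equal(length(unique(stats::na.omit(mem))), 2L)
  expect_length(unique(mem[1:6]), 1L)
  expect_length(unique(mem[7:12]), 1L)
  expect_false(unique(mem[1:6]) == unique(mem[7:12]))
  # identical seed, identical labels
  part2 <- detect_modules(net, seed = 1)
  expect_identical(part$membership, part2$membership)
})

test_that("edgeless networks yield an all-unlabelled partition", {
  r6 <- diag(6); p6 <- matrix(1, 6, 6)
  dimnames(r6) <- dimnames(p6) <- list(letters[1:6], letters[1:6])
  empty <- suppressWarnings(build_network(r6, p6))
  part <- detect_modules(empty)
  expect_true(all(is.na(part$membership$module)))
})

test_that("natural connectivity matches closed forms and the expm oracle", {
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(natural_connectivity(K3), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-10)
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(natural_connectivity(P3),
               log((exp(sqrt(2)) + 1 + exp(-sqrt(2))) / 3), tolerance = 1e-10)
  expect_equal(natural_connectivity(matrix(0, 5, 5)), 0)
  set.seed(10)
  for (i in 1:30) {
    A <- random_adjacency(sample(3:20, 1))
    expect_equal(natural_connectivity(A), nc_expm_oracle(A), tolerance = 1e-8)
  }
})

test_that("removing an edge never increases natural connectivity", {
  set.seed(11)
  for (i in 1:100) {
    A <- random_adjacency(sample(4:15, 1), p = 0.4)
    edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    if (nrow(edges) == 0L) next
    e <- edges[sample(nrow(edges), 1), ]
    B <- A; B[e[1], e[2]] <- B[e[2], e[1]] <- 0
    expect_lte(natural_connectivity(B), natural_connectivity(A) + 1e-12)
  }
})

test_that("robustness curves: zero fraction is intact, complete graphs are closed-form", {
  K8 <- matrix(1, 8, 8) - diag(8)
  nc_K <- function(m) log((exp(m - 1) + (m - 1) * exp(-1)) / m)
  rc <- robustness_curve(K8, fractions = c(0, 0.25, 0.5), n_reps = 3, seed = 1)
  expect_equal(rc$curve$mean[rc$curve$fraction == 0], nc_K(8))
  # removing k nodes from K8 leaves K_{8-k}, independent of which nodes
  expect_equal(rc$curve$mean[rc$curve$fraction == 0.25], nc_K(6))
  expect_equal(rc$curve$sd[rc$curve$fraction == 0.25], 0)
  expect_equal(rc$curve$mean[rc$curve$fraction == 0.5], nc_K(4))
  expect_error(robustness_curve(K8, fractions = 0.99), "every node")
})

test_that("mean robustness curves decline with removal fraction on random graphs", {
  set.seed(12)
  A <- random_adjacency(50, p = 0.2)
  rc <- robustness_curve(A, fractions = seq(0.1, 0.6, 0.1), n_reps = 50,
                         seed = 2)
  expect_true(all(diff(rc$curve$mean) < 0))
  expect_true(all(rc$curve$sd >= 0))
  expect_gt(robustness_auc(rc), 0)
})

test_that("robustness removal counts round half away from zero reproducibly", {
  A <- random_adjacency(10, p = 0.5)
  rc <- robustness_curve(A, fractions = c(0.25, 0.35), n_reps = 2, seed = 9)
  expect_equal(rc$curve$n_removed, c(3L, 4L))   # 2.5 -> 3, 3.5 -> 4
  rc2 <- robustness_curve(A, fractions = c(0.25, 0.35), n_reps = 2, seed = 9)
  expect_identical(rc$curve, rc2$curve)
})
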