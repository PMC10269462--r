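# Eigengenes, module-trait correlations and hub identification.

ra_from <- function(m) sweep(m, 2, colSums(m), "/")

test_that("a rank-one module yields its shared profile with full variance explained", {
  s <- exp(sin(1:12))                      # one positive profile
  m <- rbind(t1 = s, t2 = 3 * s, t3 = 0.5 * s, filler = rep(1, 12))
  colnames(m) <- paste0("s", 1:12)
  eg <- module_eigengene(m, c("t1", "t2", "t3"), transform = "none")
  expect_equal(eg$var_explained, 1, tolerance = 1e-10)
  expect_equal(abs(mean(eg$scores)), 0, tolerance = 1e-10)
  # eigengene tracks the common profile (up to affine scale)
  expect_equal(abs(cor(eg$scores, s)), 1, tolerance = 1e-8)
  # orientation: positively correlated with mean standardised abundance
  expect_gt(cor(eg$scores, scale(s)[, 1]), 0)
})

test_that("two orthogonal profiles split variance equally", {
  n <- 8
  a <- scale(sin(seq(0, 2 * pi, length.out = n)))[, 1]
  b <- scale(cos(seq(0, 2 * pi, length.out = n)))[, 1]
  b <- scale(stats::resid(stats::lm(b ~ a)))[, 1]      # exact orthogonality
  m <- rbind(t1 = a + 10, t2 = b + 10)
  colnames(m) <- paste0("s", 1:n)
  eg <- module_eigengene(m, c("t1", "t2"), transform = "none")
  expect_equal(eg$var_explained, 0.5, tolerance = 1e-8)
})

test_that("eigengene is invariant to taxon order and positive rescaling", {
  com <- generate_counts(tiny_scenario(14))
  ra <- to_relative_abundance(com$counts)
  mem <- com$truth$modules[[1]]
  e1 <- module_eigengene(ra, mem)
  e2 <- module_eigengene(ra, rev(mem))
  expect_equal(e1$scores, e2$scores, tolerance = 1e-8)
  # rescale one member's abundance profile by a positive constant: the
  # per-taxon pseudocount and standardisation absorb it exactly
  ra2 <- ra
  ra2[mem[1], ] <- ra2[mem[1], ] * 50
  e3 <- module_eigengene(ra2, mem)
  expect_equal(e1$scores, e3$scores, tolerance = 1e-10)
  ra3 <- ra
  ra3[mem[2], ] <- ra3[mem[2], ] * 0.001
  e4 <- module_eigengene(ra3, mem)
  expect_equal(e1$scores, e4$scores, tolerance = 1e-10)
})

test_that("constant member profiles are dropped, collapsing modules error", {
  m <- rbind(t1 = c(5, 6, 7, 8), t2 = c(8, 7, 6, 5), t3 = c(2, 2, 2, 2))
  colnames(m) <- paste0("s", 1:4)
  ra <- m / rep(colSums(m), each = 3)
  expect_warning(eg <- module_eigengene(ra, c("t1", "t2", "t3"),
                                        transform = "none"),
                 "constant")
  expect_equal(eg$n_members, 2L)
  expect_error(suppressWarnings(
    module_eigengene(ra, c("t1", "t3"), transform = "none")),
    "below 2")
})

test_that("module-trait correlations hit the exact r = +/-1 cases", {
  com <- generate_counts(tiny_scenario(15))
  ra <- to_relative_abundance(com$counts)
  eg <- module_eigengene(ra, com$truth$modules[[1]])
  vars <- data.frame(up = eg$scores, down = -eg$scores + 3)
  mt <- correlate_modules(list(m1 = eg), vars)
  expect_equal(mt$r["m1", "up"], 1, tolerance = 1e-10)
  expect_equal(mt$r["m1", "down"], -1, tolerance = 1e-10)
  expect_lt(mt$p["m1", "up"], 1e-10)
})

test_that("correlation entries match a direct formula evaluation", {
  set.seed(16)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    E <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("m1", "m2")))
    vars <- data.frame(v1 = rnorm(n), v2 = rnorm(n))
    mt <- correlate_modules(E, vars)
    for (m in 1:2) for (v in 1:2) {
      x <- E[, m]; y <- vars[[v]]
      r_direct <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(mt$r[m, v], r_direct, tolerance = 1e-10)
    }
  }
})

test_that("missing trait values are pairwise-deleted and counted", {
  E <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "m1"))
  vars <- data.frame(v = c(NA, rnorm(8), NA), flat = rep(2, 10))
  mt <- correlate_modules(E, vars)
  expect_equal(mt$table$n[mt$table$variable == "v"], 8)
  expect_true(is.na(mt$r["m1", "flat"]))     # zero-variance variable
})

test_that("the star centre is the unique hub and leaves score zero", {
  ids <- c("hub", paste0("leaf", 1:5))
  rho <- diag(6); p <- matrix(1, 6, 6)
  dimnames(rho) <- dimnames(p) <- list(ids, ids)
  for (l in 2:6) {
    rho[1, l] <- rho[l, 1] <- 0.9; p[1, l] <- p[l, 1] <- 1e-4
  }
  net <- build_network(rho, p)
  hb <- hub_nodes(net, top_fraction = 0.1)
  expect_equal(hb$betweenness[hb$node == "hub"], 1)
  expect_true(all(hb$betweenness[hb$node != "hub"] == 0))
  expect_identical(hb$node[hb$hub], "hub")
})

test_that("cycle symmetry keeps all tied nodes flagged together", {
  n <- 10; ids <- paste0("c", 1:n)
  rho <- diag(n); p <- matrix(1, n, n)
  dimnames(rho) <- dimnames(p) <- list(ids, ids)
  for (i in 1:n) {
    j <- i %% n + 1
    rho[i, j] <- rho[j, i] <- 0.9; p[i, j] <- p[j, i] <- 1e-4
  }
  net <- build_network(rho, p)
  hb <- hub_nodes(net, top_fraction = 0.1)
  expect_true(all(hb$hub))                  # perfect ties keep everyone
})

test_that("betweenness agrees with exhaustive path enumeration on small graphs", {
  set.seed(17)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    A <- random_adjacency(n, p = 0.45)
    ids <- paste0("v", 1:n)
    rho <- diag(n); p <- matrix(1, n, n)
    dimnames(rho) <- dimnames(p) <- dimnames(A) <- list(ids, ids)
    rho[A > 0] <- 0.9; p[A > 0] <- 1e-4
    net <- build_network(rho, p)
    hb <- hub_nodes(net)
    expect_equal(hb$betweenness, betweenness_oracle(A), tolerance = 1e-10)
  }
})
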