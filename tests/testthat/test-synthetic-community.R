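# The synthetic community generator: contracts, reproducibility, and the
# statistical structure it promises downstream stages.

test_that("generated tables have the promised shape, sign and alignment", {
  com <- generate_counts(default_scenario(1))
  expect_identical(dim(com$counts), c(200L, 24L))
  expect_true(all(com$counts >= 0))
  expect_true(is.integer(com$counts))
  expect_identical(colnames(com$counts), com$metadata$sample_id)
  expect_setequal(rownames(com$counts), com$taxonomy$taxon_id)
  # focal genus annotated and enriched under coating
  tri <- collapse_genus(com$counts, com$taxonomy, "Trichoderma")
  expect_length(tri$members, 3L)
  ra <- to_relative_abundance(com$counts)
  f <- colSums(ra[tri$members, , drop = FALSE])
  coated <- com$metadata$treatment == "coated"
  expect_gt(mean(f[coated]), mean(f[!coated]))
})

test_that("generation is reproducible from the seed and sensitive to it", {
  a <- generate_counts(tiny_scenario(7))
  b <- generate_counts(tiny_scenario(7))
  c <- generate_counts(tiny_scenario(8))
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_false(identical(a$counts, c$counts))
})

test_that("sample totals follow the configured depth distribution support", {
  sc <- tiny_scenario(3)
  com <- generate_counts(sc)
  totals <- colSums(com$counts)
  expect_true(all(totals >= ceiling(sc$sequencing_depth_mean / 20)))
  # overdispersed but centred near the mean depth
  expect_gt(mean(totals), 0.6 * sc$sequencing_depth_mean)
  expect_lt(mean(totals), 1.6 * sc$sequencing_depth_mean)
})

test_that("a zero-loading module is statistically inert", {
  sc <- synthetic_scenario(
    n_taxa = 40, n_samples_per_group = 30,
    groups = data.frame(crop = "maize", treatment = "coated"),
    modules = list(module_spec(size = 10, loading = 0)),
    sequencing_depth_mean = 2e4, seed = 11)
  com <- generate_counts(sc)
  ra <- to_relative_abundance(com$counts)
  sm <- suppressWarnings(spearman_matrix(ra))
  mem <- com$truth$modules[[1]]
  inmod <- rownames(ra) %in% mem
  within <- sm$rho[inmod, inmod][upper.tri(diag(sum(inmod)))]
  between <- sm$rho[!inmod, !inmod][upper.tri(diag(sum(!inmod)))]
  # same magnitude of correlation as unrelated taxa
  expect_lt(abs(mean(within) - mean(between)), 0.1)
})

test_that("planted-module members are strongly rank-correlated under activity", {
  # one rep of the high-signal regime; the acceptance suite repeats this
  com <- generate_counts(recovery_scenario(21))
  meta <- com$metadata
  smp <- meta$sample_id[meta$treatment == "coated"]
  ra <- to_relative_abundance(com$counts[, smp])
  mem <- com$truth$modules[[1]]
  rho <- suppressWarnings(spearman_matrix(ra[mem, ]))$rho
  expect_gt(mean(rho[upper.tri(rho)]), 0.8)
  # inactive in the control group: no such structure
  ctl <- meta$sample_id[meta$treatment == "control"]
  rho0 <- suppressWarnings(
    spearman_matrix(to_relative_abundance(com$counts[, ctl])[mem, ]))$rho
  expect_lt(mean(rho0[upper.tri(rho0)]), 0.3)
})

test_that("focal enrichment raises coated relative abundance monotonically", {
  means <- vapply(c(1, 3, 9), function(enr) {
    sc <- tiny_scenario(5)
    sc$focal_enrichment <- enr
    com <- generate_counts(sc)
    ra <- to_relative_abundance(com$counts)
    tri <- collapse_genus(com$counts, com$taxonomy, sc$focal_genus)
    mean(colSums(ra[tri$members, com$metadata$treatment == "coated",
                    drop = FALSE]))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("without competition the negative-significant rate matches a permuted null", {
  sc <- synthetic_scenario(
    n_taxa = 60, n_samples_per_group = 12,
    groups = data.frame(crop = "maize", treatment = c("coated", "control")),
    modules = list(), competition_strength = 0,
    focal_enrichment = 1, sequencing_depth_mean = 2e4, seed = 31)
  com <- generate_counts(sc)
  smp <- com$metadata$sample_id[com$metadata$treatment == "coated"]
  ra <- to_relative_abundance(com$counts[, smp])
  sm <- suppressWarnings(spearman_matrix(ra))
  neg_rate <- function(rho, p) {
    ut <- upper.tri(rho)
    mean(rho[ut] < -0.8 & p[ut] < 0.05, na.rm = TRUE)
  }
  obs <- neg_rate(sm$rho, sm$p)
  # permuted-label null: shuffle each taxon's samples independently
  null_rates <- vapply(1:20, function(i) {
    perm <- apply(ra, 1L, sample)        # samples x taxa, broken coupling
    smn <- suppressWarnings(spearman_matrix(t(perm)))
    neg_rate(smn$rho, smn$p)
  }, 0)
  expect_lt(abs(obs - mean(null_rates)),
            max(0.002, 3 * stats::sd(null_rates)))
})

test_that("scenario validation rejects inconsistent module specs", {
  expect_error(synthetic_scenario(n_taxa = 10,
                                  modules = list(module_spec(8, 0.8),
                                                 module_spec(8, 0.8))),
               "exceed n_taxa")
  expect_error(synthetic_scenario(n_focal_otus = 5,
                                  modules = list(module_spec(4, 0.8,
                                                             focal = TRUE))),
               "larger than n_focal_otus")
  expect_error(synthetic_scenario(traits = list(trait_spec("x", 3))),
               "undefined module")
  expect_error(module_spec(5, 1.2), "loading")
})

test_that("the fixture suite is deterministic and contains both scenarios", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- generate_fixture_suite(d1, seed = 7)
  p2 <- generate_fixture_suite(d2, seed = 7)
  expect_identical(basename(p1), basename(p2))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  expect_true(any(grepl("null_counts", p1)))
  expect_true(any(grepl("planted_counts", p1)))
  d3 <- file.path(tempdir(), "fx3")
  p3 <- generate_fixture_suite(d3, seed = 8)
  expect_false(identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p3))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})
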