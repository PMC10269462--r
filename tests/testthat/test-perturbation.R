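# Knockout operations: removal, reduction to control abundance, and
# shared-node module matching.

test_that("genus removal drops exactly the member rows and is idempotent", {
  com <- generate_counts(tiny_scenario(18))
  tri <- collapse_genus(com$counts, com$taxonomy, "Trichoderma")
  out <- knockout_remove(com$counts, com$taxonomy, "Trichoderma")
  expect_equal(nrow(out), nrow(com$counts) - length(tri$members))
  expect_false(any(tri$members %in% rownames(out)))
  keep <- setdiff(rownames(com$counts), tri$members)
  expect_identical(out[keep, ], com$counts[keep, ])     # non-members untouched
  expect_warning(again <- knockout_remove(out, com$taxonomy, "Trichoderma"))
  expect_identical(again, out)                          # idempotent
})

test_that("reduction scales coated samples to the control mean abundance", {
  com <- generate_counts(tiny_scenario(19))
  meta <- com$metadata
  out <- knockout_reduce(com$counts, com$taxonomy, "Trichoderma", meta)
  tri <- collapse_genus(com$counts, com$taxonomy, "Trichoderma")
  ctl <- meta$sample_id[meta$treatment == "control"]
  coat <- meta$sample_id[meta$treatment == "coated"]
  # control columns byte-identical
  expect_identical(out[, ctl], com$counts[, ctl])
  # post-hoc coated mean relative abundance matches control within rounding
  ra_out <- to_relative_abundance(out)
  ra_in <- to_relative_abundance(com$counts)
  m_ctrl <- mean(colSums(ra_in[tri$members, ctl, drop = FALSE]))
  m_coat <- mean(colSums(ra_out[tri$members, coat, drop = FALSE]))
  expect_equal(m_coat, m_ctrl, tolerance = 0.05)
  # non-member rows in coated samples untouched
  keep <- setdiff(rownames(out), tri$members)
  expect_identical(out[keep, coat], com$counts[keep, coat])
})

test_that("reduction boundary cases: equal means no-op, absent control zeroes", {
  m <- matrix(c(40L, 100L, 40L, 100L), 2, 2,
              dimnames = list(c("t1", "t2"), c("c1", "k1")))
  tax <- data.frame(taxon_id = c("t1", "t2"), genus = c("Trichoderma", "Other"))
  meta <- data.frame(sample_id = c("c1", "k1"),
                     treatment = c("coated", "control"))
  same <- knockout_reduce(m, tax, "Trichoderma", meta)
  expect_identical(same, m)                      # equal means -> unchanged
  m2 <- m; m2["t1", "k1"] <- 0L
  zeroed <- knockout_reduce(m2, tax, "Trichoderma", meta)
  expect_equal(zeroed["t1", "c1"], 0L)           # absent in control -> zero
})

test_that("module matching implements the shared-node proportion with tie-breaks", {
  part <- structure(list(membership = data.frame(
    node = c("A", "B", "C", "D", "E", "F", "G", "H", "I"),
    module = c(NA, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)),
    modularity = 0.5, seed = 1, min_module_size = 2,
    algorithm = "infomap"), class = "module_partition")
  m <- match_modules(c("A", "B", "C", "D"), part)
  expect_equal(m$best_module, 1L)
  expect_equal(m$shared_proportion, 0.75)        # A present but unclustered
  expect_equal(m$jaccard, 3 / 5)
  disj <- match_modules(c("X", "Y"), part)
  expect_equal(disj$shared_proportion, 0)
  ident <- match_modules(c("F", "G", "H", "I"), part)
  expect_equal(ident$shared_proportion, 1)
  # tie between modules 1 and 2 -> smaller id wins
  tie <- match_modules(c("B", "F"), part)
  expect_equal(tie$best_module, 1L)
})

test_that("matching proportion is monotone under module merging", {
  set.seed(20)
  for (i in 1:10) {
    nodes <- paste0("n", 1:20)
    mods <- sample(1:4, 20, replace = TRUE)
    target <- sample(nodes, 8)
    part <- structure(list(membership = data.frame(node = nodes, module = mods),
                           modularity = 0, seed = 1, min_module_size = 1,
                           algorithm = "infomap"), class = "module_partition")
    merged <- part
    merged$membership$module[merged$membership$module == 2L] <- 1L
    expect_gte(match_modules(target, merged)$shared_proportion,
               match_modules(target, part)$shared_proportion)
  }
})

test_that("focal knockout dissolves the nucleated module; sham knockout spares it", {
  com <- generate_counts(knockout_scenario(42))
  meta <- com$metadata
  smp <- meta$sample_id[meta$treatment == "coated"]
  ko <- suppressWarnings(
    knockout_experiment(com$counts, com$taxonomy, meta, "Trichoderma",
                        samples = smp, seed = 1))
  expect_setequal(names(ko$modes), c("remove", "reduce"))
  expect_lt(ko$modes$remove$shared_proportion, 0.5)
  expect_false(ko$modes$remove$persistent)
  # most of the planted module is the detected target
  expect_gt(length(intersect(ko$target_module, com$truth$modules[[1]])), 4)
  # sham: a genus entirely outside the target module
  gen <- split(com$taxonomy$taxon_id, com$taxonomy$genus)
  sham <- setdiff(sort(names(gen)[!vapply(gen, function(v)
    any(v %in% ko$target_module), TRUE)]), "Trichoderma")[1]
  ko2 <- suppressWarnings(
    knockout_experiment(com$counts, com$taxonomy, meta, sham,
                        samples = smp, target = ko$target_module,
                        modes = "remove", seed = 1))
  expect_gte(ko2$modes$remove$shared_proportion, 0.5)
  expect_true(ko2$modes$remove$persistent)
})

test_that("a module not involving the focal genus survives focal removal intact", {
  sc <- synthetic_scenario(
    n_taxa = 120, n_samples_per_group = 40,
    groups = data.frame(crop = "maize", treatment = c("coated", "control")),
    modules = list(module_spec(size = 7, loading = 0.85, focal = TRUE,
                               focal_loading = 0.97,
                               member_residual_cor = -0.3),
                   module_spec(size = 10, loading = 0.95)),
    focal_enrichment = 4, focal_baseline = -1.5,
    sequencing_depth_mean = 1e5, seed = 55)
  com <- generate_counts(sc)
  meta <- com$metadata
  smp <- meta$sample_id[meta$treatment == "coated"]
  net <- suppressWarnings(group_network(com$counts, smp))
  part <- detect_modules(net, seed = 1)
  bystander <- com$truth$modules[[2]]
  # locate the detected module carrying the bystander taxa
  mem <- part$membership
  tb <- table(mem$module[mem$node %in% bystander])
  target <- module_members(part, as.integer(names(which.max(tb))))
  tab2 <- knockout_remove(com$counts, com$taxonomy, "Trichoderma")
  net2 <- suppressWarnings(group_network(tab2, smp))
  part2 <- detect_modules(net2, seed = 1)
  m <- match_modules(target, part2)
  expect_equal(m$shared_proportion, 1)
})
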