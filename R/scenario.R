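# Synthetic rhizosphere community generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a log-normal baseline of OTU abundances, planted correlated
# modules driven by per-sample latent factors, a focal inoculant genus
# enriched only in coated groups, negatively coupled taxon pairs
# ("competition") active under coating, multinomial read sampling at an
# overdispersed depth, and plant traits / enzyme activities that are linear
# in a module's latent factor.

#' Declare a planted module for a synthetic scenario
#'
#' A module is a set of taxa whose (log-scale) abundances share a per-sample
#' latent factor. For an ordinary module every member has the same loading,
#' so each member pair has latent correlation equal to `loading`. A focal
#' module additionally contains the focal inoculant OTUs, which sit on the
#' factor with loading `focal_loading`; ordinary members then correlate with
#' the focal OTUs at `sqrt(loading * focal_loading)` while correlating with
#' each other only at `loading + (1 - loading) * member_residual_cor` —
#' the star-like ("focal-nucleated") structure in which the module is held
#' together by the inoculant rather than by member-member association.
#'
#' @param size Number of member taxa (for a focal module this includes the
#'   focal OTUs).
#' @param loading Latent-factor loading in \[0, 1\]; equals the member-member
#'   latent correlation of an ordinary module.
#' @param focal Logical; is this the module nucleated by the focal genus?
#' @param active `"all"` (factor active in every group) or `"coated"`
#'   (factor active only in coated groups). Defaults to `"coated"` for focal
#'   modules and `"all"` otherwise.
#' @param focal_loading Loading of the focal OTUs themselves (focal modules
#'   only).
#' @param member_residual_cor Exchangeable correlation of the member residuals
#'   in a focal module; slightly negative values keep member-member
#'   correlations near the feasibility floor so the module genuinely depends
#'   on the focal OTUs. `NULL` picks `-0.9 / n_members`, safely above the
#'   exchangeable-correlation lower bound `-1 / (n_members - 1)`.
#' @return A `module_spec` list.
#' @export
module_spec <- function(size, loading, focal = FALSE,
                        active = if (focal) "coated" else "all",
                        focal_loading = 0.97,
                        member_residual_cor = NULL) {
  stopifnot(size >= 2, loading >= 0, loading <= 1,
            focal_loading > 0, focal_loading <= 1)
  active <- match.arg(active, c("all", "coated"))
  structure(list(size = as.integer(size), loading = loading, focal = focal,
                 active = active, focal_loading = focal_loading,
                 member_residual_cor = member_residual_cor),
            class = "module_spec")
}

#' Declare a trait or enzyme variable coupled to a planted module
#'
#' The variable is generated as
#' `baseline + coupling * f + rnorm(0, noise_sd)` where `f` is the coupled
#' module's latent factor (0 in samples where the module is inactive). With
#' the default `noise_sd = sqrt(1 - coupling^2)` the generating correlation
#' between the variable and the factor equals `coupling` in samples where
#' the module is active, so `coupling = -0.6` yields a disease-incidence
#' style variable that falls when the module is up.
#'
#' @param name Variable name (column in the sample metadata).
#' @param module Index of the coupled module in the scenario's module list,
#'   or `NA` for a pure-noise variable.
#' @param coupling Coupling coefficient in \[-1, 1\] (the generating
#'   correlation under the default noise).
#' @param noise_sd Gaussian noise standard deviation; `NULL` for
#'   `sqrt(1 - coupling^2)`.
#' @param baseline Additive constant (units of the measured variable).
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, module = 1L, coupling = 0.8, noise_sd = NULL,
                       baseline = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            abs(coupling) <= 1)
  if (is.null(noise_sd)) noise_sd <- sqrt(max(0, 1 - coupling^2))
  structure(list(name = name, module = module, coupling = coupling,
                 noise_sd = noise_sd, baseline = baseline),
            class = "trait_spec")
}

#' Define a synthetic community scenario
#'
#' Bundles every knob of the generator into a validated object. All
#' randomness downstream derives from `seed`.
#'
#' @param n_taxa Number of OTUs.
#' @param n_samples_per_group Replicates per (crop, treatment) group.
#' @param groups Data frame with columns `crop` and `treatment`
#'   (`"coated"`/`"control"`), one row per group.
#' @param modules List of [module_spec()] entries; member counts must sum to
#'   at most `n_taxa`.
#' @param focal_genus Genus label of the inoculant.
#' @param n_focal_otus Number of OTUs annotated to the focal genus (placed in
#'   the focal module if one exists, else the first OTUs).
#' @param focal_enrichment Multiplicative abundance enrichment of the focal
#'   OTUs in coated groups (1 = none).
#' @param competition_strength Fraction of non-module taxa arranged into
#'   negatively coupled pairs in coated groups (0 = none).
#' @param competition_cor Latent correlation of a competing pair in coated
#'   samples (negative).
#' @param sequencing_depth_mean Mean reads per sample.
#' @param overdispersion Depth overdispersion `phi` (> 0): sample totals are
#'   negative-binomial with variance `mu + phi * mu^2`.
#' @param baseline_sd SD of per-taxon baseline log-abundances.
#' @param taxon_sd SD of the per-sample log-abundance fluctuation (the
#'   latent signal) common to all taxa.
#' @param focal_baseline Fixed baseline log-abundance of the focal OTUs
#'   (keeps the inoculant's relative abundance in a realistic sub-percent
#'   range before enrichment).
#' @param module_baseline,module_baseline_sd Mean and SD of the baseline
#'   log-abundance of planted-module members. Kept below the community
#'   average so planted modules stay minor components (a few percent of
#'   reads): were a module a dominant share, the compositional closure of
#'   the multinomial denominator would co-vary with its latent factor and
#'   attenuate the very correlations being planted.
#' @param otus_per_genus OTUs per synthetic genus in the taxonomy.
#' @param traits List of [trait_spec()] entries.
#' @param seed Integer master seed.
#' @return A validated `synthetic_scenario` object.
#' @seealso [generate_counts()], [default_scenario()]
#' @export
synthetic_scenario <- function(n_taxa = 200,
                               n_samples_per_group = 6,
                               groups = data.frame(
                                 crop = rep(c("maize", "watermelon"), each = 2),
                                 treatment = rep(c("coated", "control"), 2)),
                               modules = list(),
                               focal_genus = "Trichoderma",
                               n_focal_otus = 3,
                               focal_enrichment = 4,
                               competition_strength = 0,
                               competition_cor = -0.95,
                               sequencing_depth_mean = 2e4,
                               overdispersion = 0.02,
                               baseline_sd = 1,
                               taxon_sd = 1,
                               focal_baseline = 0,
                               module_baseline = -1,
                               module_baseline_sd = 0.3,
                               otus_per_genus = 3,
                               traits = list(),
                               seed = 1) {
  stopifnot(n_taxa >= 2, n_samples_per_group >= 1,
            is.data.frame(groups), all(c("crop", "treatment") %in% names(groups)),
            sequencing_depth_mean > 0, overdispersion > 0,
            focal_enrichment > 0, competition_strength >= 0,
            competition_cor >= -1, competition_cor <= 0,
            n_focal_otus >= 1, otus_per_genus >= 1)
  if (!all(groups$treatment %in% c("coated", "control")))
    stop("group treatments must be 'coated' or 'control'", call. = FALSE)
  if (length(modules)) {
    if (!all(vapply(modules, inherits, TRUE, "module_spec")))
      stop("modules must be a list of module_spec() entries", call. = FALSE)
    sizes <- vapply(modules, `[[`, 1L, "size")
    if (sum(sizes) > n_taxa)
      stop("module member counts exceed n_taxa", call. = FALSE)
    if (sum(vapply(modules, `[[`, TRUE, "focal")) > 1L)
      stop("at most one focal module is allowed", call. = FALSE)
    focal_idx <- which(vapply(modules, `[[`, TRUE, "focal"))
    if (length(focal_idx) && modules[[focal_idx]]$size <= n_focal_otus)
      stop("focal module must be larger than n_focal_otus", call. = FALSE)
  }
  if (length(traits)) {
    if (!all(vapply(traits, inherits, TRUE, "trait_spec")))
      stop("traits must be a list of trait_spec() entries", call. = FALSE)
    mod_ids <- vapply(traits, `[[`, 1, "module")
    bad <- !is.na(mod_ids) & (mod_ids < 1 | mod_ids > length(modules))
    if (any(bad))
      stop("trait coupled to undefined module: ",
           paste(vapply(traits[bad], `[[`, "", "name"), collapse = ", "),
           call. = FALSE)
  }
  structure(list(n_taxa = as.integer(n_taxa),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 groups = groups, modules = modules,
                 focal_genus = focal_genus,
                 n_focal_otus = as.integer(n_focal_otus),
                 focal_enrichment = focal_enrichment,
                 competition_strength = competition_strength,
                 competition_cor = competition_cor,
                 sequencing_depth_mean = sequencing_depth_mean,
                 overdispersion = overdispersion,
                 baseline_sd = baseline_sd, taxon_sd = taxon_sd,
                 focal_baseline = focal_baseline,
                 module_baseline = module_baseline,
                 module_baseline_sd = module_baseline_sd,
                 otus_per_genus = as.integer(otus_per_genus),
                 traits = traits, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# Exchangeable-correlation Cholesky factor for module member residuals.
.exch_chol <- function(k, rho) {
  if (k == 1L) return(matrix(1, 1, 1))
  if (rho <= -1 / (k - 1))
    stop("member_residual_cor below the exchangeable feasibility bound",
         call. = FALSE)
  S <- matrix(rho, k, k); diag(S) <- 1
  chol(S)
}

#' Generate a synthetic OTU table with taxonomy, metadata and ground truth
#'
#' Draws counts by (i) per-taxon log-normal baselines, (ii) module latent
#' factors added on the log scale, (iii) focal-genus enrichment in coated
#' groups, (iv) negatively coupled latent pairs in coated groups, and
#' (v) multinomial read sampling at a negative-binomial depth. Traits are
#' linear in the coupled module's factor plus Gaussian noise. Fully
#' reproducible from `scenario$seed`.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list of class `synthetic_community` with elements
#'   `counts` (integer matrix, taxa x samples), `taxonomy` (data frame),
#'   `metadata` (data frame with design columns and trait values), and
#'   `truth` (planted module membership, focal OTU ids, per-sample module
#'   factors, competition pairs).
#' @export
generate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  G <- nrow(sc$groups)
  n <- G * sc$n_samples_per_group
  taxa <- sprintf("OTU_%03d", seq_len(sc$n_taxa))

  design <- data.frame(
    sample_id = character(n), crop = character(n), treatment = character(n),
    replicate = integer(n), stringsAsFactors = FALSE)
  idx <- 1L
  for (g in seq_len(G)) {
    for (r in seq_len(sc$n_samples_per_group)) {
      design$crop[idx] <- sc$groups$crop[g]
      design$treatment[idx] <- sc$groups$treatment[g]
      design$replicate[idx] <- r
      design$sample_id[idx] <- sprintf("%s_%s_%02d", sc$groups$crop[g],
                                       sc$groups$treatment[g], r)
      idx <- idx + 1L
    }
  }
  coated <- design$treatment == "coated"

  # assign module membership in consecutive blocks; focal OTUs lead their module
  members <- vector("list", length(sc$modules))
  cursor <- 1L
  focal_module <- which(vapply(sc$modules, `[[`, TRUE, "focal"))
  for (m in seq_along(sc$modules)) {
    members[[m]] <- cursor:(cursor + sc$modules[[m]]$size - 1L)
    cursor <- cursor + sc$modules[[m]]$size
  }
  focal_otus <- if (length(focal_module)) {
    members[[focal_module]][seq_len(sc$n_focal_otus)]
  } else seq_len(min(sc$n_focal_otus, sc$n_taxa))
  in_module <- if (length(members)) unlist(members) else integer(0)
  free <- setdiff(seq_len(sc$n_taxa), union(in_module, focal_otus))

  out <- with_seed(sc$seed, {
    mu <- stats::rnorm(sc$n_taxa, 0, sc$baseline_sd)
    if (length(in_module))
      mu[in_module] <- stats::rnorm(length(in_module), sc$module_baseline,
                                    sc$module_baseline_sd)
    mu[focal_otus] <- sc$focal_baseline
    Z <- matrix(stats::rnorm(sc$n_taxa * n), sc$n_taxa, n)
    L <- Z

    factors <- matrix(0, n, max(1L, length(sc$modules)))
    for (m in seq_along(sc$modules)) {
      mod <- sc$modules[[m]]
      act <- if (mod$active == "all") rep(TRUE, n) else coated
      f <- stats::rnorm(n)           # drawn for all samples to keep the
      f[!act] <- 0                   # stream layout independent of activity
      factors[, m] <- f
      mem <- members[[m]]
      if (mod$focal) {
        foc <- mem[seq_len(sc$n_focal_otus)]
        ord <- setdiff(mem, foc)
        k <- length(ord)
        cres <- if (is.null(mod$member_residual_cor)) -0.9 / k else
          mod$member_residual_cor
        U <- .exch_chol(k, cres)     # residuals with exchangeable correlation
        resid <- t(U) %*% Z[ord, act, drop = FALSE]
        L[foc, act] <- sqrt(mod$focal_loading) * rep(f[act], each = length(foc)) +
          sqrt(1 - mod$focal_loading) * Z[foc, act, drop = FALSE]
        L[ord, act] <- sqrt(mod$loading) * rep(f[act], each = k) +
          sqrt(1 - mod$loading) * resid
      } else {
        k <- length(mem)
        L[mem, act] <- sqrt(mod$loading) * rep(f[act], each = k) +
          sqrt(1 - mod$loading) * Z[mem, act, drop = FALSE]
      }
    }

    # competition: negatively coupled latent pairs, active only under coating
    pairs <- NULL
    n_pairs <- floor(sc$competition_strength * length(free) / 2)
    if (n_pairs > 0) {
      shuffled <- sample(free)
      pairs <- matrix(shuffled[seq_len(2 * n_pairs)], ncol = 2, byrow = TRUE)
      rho <- sc$competition_cor
      for (q in seq_len(n_pairs)) {
        i <- pairs[q, 1L]; j <- pairs[q, 2L]
        L[j, coated] <- rho * L[i, coated] +
          sqrt(1 - rho^2) * Z[j, coated]
      }
    }

    X <- mu + sc$taxon_sd * L
    if (sc$focal_enrichment != 1)
      X[focal_otus, coated] <- X[focal_otus, coated] + log(sc$focal_enrichment)

    size <- 1 / sc$overdispersion
    depth <- pmax(stats::rnbinom(n, mu = sc$sequencing_depth_mean, size = size),
                  ceiling(sc$sequencing_depth_mean / 20))
    counts <- matrix(0L, sc$n_taxa, n, dimnames = list(taxa, design$sample_id))
    for (s in seq_len(n)) {
      p <- exp(X[, s] - max(X[, s]))
      counts[, s] <- stats::rmultinom(1, depth[s], p)[, 1L]
    }

    meta <- design
    for (tr in sc$traits) {
      f <- if (is.na(tr$module)) rep(0, n) else factors[, tr$module]
      meta[[tr$name]] <- tr$baseline + tr$coupling * f +
        stats::rnorm(n, 0, tr$noise_sd)
    }
    list(counts = counts, metadata = meta, factors = factors, pairs = pairs)
  })

  genus_of <- character(sc$n_taxa)
  genus_of[focal_otus] <- sc$focal_genus
  rest <- setdiff(seq_len(sc$n_taxa), focal_otus)
  genus_of[rest] <- sprintf("Genus_%03d",
                            ceiling(seq_along(rest) / sc$otus_per_genus))
  taxonomy <- data.frame(
    taxon_id = taxa,
    kingdom = "Fungi",
    phylum = sprintf("Phylum_%02d", (seq_len(sc$n_taxa) - 1L) %/% 50L + 1L),
    class = sprintf("Class_%02d", (seq_len(sc$n_taxa) - 1L) %/% 25L + 1L),
    order = sprintf("Order_%02d", (seq_len(sc$n_taxa) - 1L) %/% 12L + 1L),
    family = sprintf("Family_%02d", (seq_len(sc$n_taxa) - 1L) %/% 6L + 1L),
    genus = genus_of,
    stringsAsFactors = FALSE)

  truth <- list(
    modules = lapply(members, function(ix) taxa[ix]),
    focal_module = if (length(focal_module)) focal_module else NA_integer_,
    focal_otus = taxa[focal_otus],
    factors = out$factors,
    competition_pairs = if (is.null(out$pairs)) NULL else
      matrix(taxa[out$pairs], ncol = 2),
    scenario = sc)

  structure(list(counts = out$counts, taxonomy = taxonomy,
                 metadata = out$metadata, truth = truth),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("synthetic_community: %d taxa x %d samples, %d planted module(s)\n",
              nrow(x$counts), ncol(x$counts), length(x$truth$modules)))
  invisible(x)
}

# ---- scenario presets -------------------------------------------------------

#' Preset scenarios emulating the seed-coating study and its checks
#'
#' `default_scenario()` is the study emulation: 200 OTUs, maize and
#' watermelon each with coated and control groups of 6 replicates, a
#' focal-nucleated module (3 *Trichoderma* OTUs plus 9 companions) active
#' only under coating, a background module shared by all groups, elevated
#' competition (negatively coupled taxon pairs) under coating, and plant
#' traits / enzyme activities coupled to the focal module with generating
#' correlations mirroring the reported module-trait pattern (growth traits
#' ~+0.8, enzymes +0.75..0.85, disease incidence -0.6).
#'
#' `null_scenario()` removes every treatment effect (no focal module, no
#' enrichment, no competition; the background module is active everywhere)
#' so group labels are exchangeable — the calibration null for PERMANOVA and
#' the rank tests.
#'
#' `recovery_scenario()` plants one 15-member module at loading 0.9 with 30
#' samples per group, the regime for membership-recovery checks.
#'
#' `trait_scenario()` is a single 60-sample coated group with a 10-member
#' module and two coupled variables (`growth_trait` +0.8,
#' `disease_incidence` -0.6) for eigengene-trait recovery checks.
#'
#' `negative_edge_scenario()` uses 12 samples per group so that edge
#' estimates are informative, with full-strength competition under coating.
#'
#' `knockout_scenario()` is the focal-nucleated regime for the in-silico
#' knockout: 60 OTUs, 50 coated and 50 control samples, a module of 3 focal
#' plus 5 companion OTUs whose mutual association exists essentially only
#' through the focal factor.
#'
#' @param seed Master seed.
#' @return A [synthetic_scenario()].
#' @name scenario_presets
NULL

#' @rdname scenario_presets
#' @export
default_scenario <- function(seed = 1) {
  synthetic_scenario(
    n_taxa = 200, n_samples_per_group = 6,
    modules = list(
      module_spec(size = 12, loading = 0.8, focal = TRUE,
                  member_residual_cor = -0.1),
      module_spec(size = 12, loading = 0.7)),
    focal_enrichment = 4, focal_baseline = -1,
    competition_strength = 1, competition_cor = -0.95,
    traits = list(
      trait_spec("plant_height", 1, 0.7, baseline = 50),
      trait_spec("root_length", 1, 0.8, baseline = 20),
      trait_spec("stem_diameter", 1, 0.8, baseline = 5),
      trait_spec("root_dry_weight", 1, 0.7, baseline = 2),
      trait_spec("shoot_dry_weight", 1, 0.7, baseline = 4),
      trait_spec("disease_incidence", 1, -0.6, baseline = 30),
      trait_spec("urease", 1, 0.75, baseline = 10),
      trait_spec("acid_phosphatase", 1, 0.78, baseline = 8),
      trait_spec("alkaline_phosphatase", 1, 0.76, baseline = 8),
      trait_spec("cellulase", 1, 0.8, baseline = 6)),
    seed = seed)
}

#' @rdname scenario_presets
#' @export
null_scenario <- function(seed = 1) {
  synthetic_scenario(
    n_taxa = 200, n_samples_per_group = 6,
    modules = list(module_spec(size = 12, loading = 0.7)),
    focal_enrichment = 1, competition_strength = 0,
    traits = list(trait_spec("plant_height", NA, 0, noise_sd = 1,
                             baseline = 50)),
    seed = seed)
}

#' @rdname scenario_presets
#' @export
recovery_scenario <- function(seed = 1) {
  synthetic_scenario(
    n_taxa = 120, n_samples_per_group = 30,
    groups = data.frame(crop = "maize",
                        treatment = c("coated", "control")),
    modules = list(module_spec(size = 15, loading = 0.9, focal = FALSE,
                               active = "coated")),
    focal_enrichment = 1, competition_strength = 0,
    sequencing_depth_mean = 1e5, module_baseline = -0.5,
    seed = seed)
}

#' @rdname scenario_presets
#' @export
trait_scenario <- function(seed = 1) {
  synthetic_scenario(
    n_taxa = 100, n_samples_per_group = 60,
    groups = data.frame(crop = "maize", treatment = "coated"),
    modules = list(module_spec(size = 10, loading = 0.9, focal = FALSE,
                               active = "all")),
    focal_enrichment = 1, competition_strength = 0,
    sequencing_depth_mean = 5e4,
    traits = list(trait_spec("growth_trait", 1, 0.8),
                  trait_spec("disease_incidence", 1, -0.6, baseline = 30)),
    seed = seed)
}

#' @rdname scenario_presets
#' @export
negative_edge_scenario <- function(seed = 1) {
  synthetic_scenario(
    n_taxa = 100, n_samples_per_group = 15,
    groups = data.frame(crop = "maize",
                        treatment = c("coated", "control")),
    modules = list(module_spec(size = 8, loading = 0.8, focal = TRUE,
                               member_residual_cor = -0.15),
                   module_spec(size = 10, loading = 0.85),
                   module_spec(size = 10, loading = 0.85)),
    focal_enrichment = 4, focal_baseline = -1,
    sequencing_depth_mean = 5e4,
    competition_strength = 1, competition_cor = -0.97,
    seed = seed)
}

#' @rdname scenario_presets
#' @export
knockout_scenario <- function(seed = 1) {
  synthetic_scenario(
    n_taxa = 120, n_samples_per_group = 50,
    groups = data.frame(crop = "maize",
                        treatment = c("coated", "control")),
    modules = list(module_spec(size = 7, loading = 0.85, focal = TRUE,
                               focal_loading = 0.97,
                               member_residual_cor = -0.3)),
    focal_enrichment = 4, focal_baseline = -1.5,
    sequencing_depth_mean = 1e5,
    competition_strength = 0,
    traits = list(trait_spec("root_length", 1, 0.8, baseline = 20),
                  trait_spec("disease_incidence", 1, -0.6, baseline = 30)),
    seed = seed)
}

#' Write a deterministic fixture suite for tests and examples
#'
#' Generates one null and one planted-module community at a reduced size and
#' writes their tables (counts, taxonomy, metadata) plus scenario
#' descriptions as tab-separated / YAML text files. Byte-identical across
#' calls with the same seed.
#'
#' @param out_dir Writable directory (created if needed).
#' @param seed Master seed.
#' @return Invisibly, the vector of file paths written.
#' @export
generate_fixture_suite <- function(out_dir, seed = 7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scens <- list(
    null = synthetic_scenario(
      n_taxa = 40, n_samples_per_group = 5,
      modules = list(module_spec(size = 8, loading = 0.7)),
      focal_enrichment = 1, competition_strength = 0,
      seed = split_seed(seed, "null")),
    planted = synthetic_scenario(
      n_taxa = 40, n_samples_per_group = 5,
      modules = list(module_spec(size = 10, loading = 0.85, focal = TRUE)),
      focal_enrichment = 4, competition_strength = 0.5,
      traits = list(trait_spec("root_length", 1, 0.8, baseline = 20),
                    trait_spec("disease_incidence", 1, -0.6, baseline = 30)),
      seed = split_seed(seed, "planted")))
  paths <- character(0)
  for (nm in names(scens)) {
    com <- generate_counts(scens[[nm]])
    p1 <- file.path(out_dir, paste0(nm, "_counts.tsv"))
    p2 <- file.path(out_dir, paste0(nm, "_taxonomy.tsv"))
    p3 <- file.path(out_dir, paste0(nm, "_metadata.tsv"))
    p4 <- file.path(out_dir, paste0(nm, "_scenario.yaml"))
    write_count_table(com$counts, p1)
    write_taxonomy(com$taxonomy, p2)
    write_sample_metadata(com$metadata, p3)
    sc <- scens[[nm]]
    yaml::write_yaml(list(
      name = nm, n_taxa = sc$n_taxa,
      n_samples_per_group = sc$n_samples_per_group,
      n_modules = length(sc$modules),
      focal_enrichment = sc$focal_enrichment,
      competition_strength = sc$competition_strength,
      seed = sc$seed), p4)
    paths <- c(paths, p1, p2, p3, p4)
  }
  invisible(paths)
}
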