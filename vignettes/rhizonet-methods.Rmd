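---
title: "Methods: co-occurrence networks, module eigengenes and the focal-genus knockout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, module eigengenes and the focal-genus knockout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rhizonet studies a question from microbial ecology: when a beneficial fungus
(*Trichoderma*) is delivered to a crop as a seed coating, does it reorganise
the rhizosphere community — tightening a module of companion taxa around
itself, raising competitive (negative) associations, stabilising the network —
and is that module the conduit through which the inoculant improves soil
enzyme activities and plant health? The package implements each analysis
stage as a tested function, plus a synthetic community generator so the whole
chain can be validated against known ground truth. This vignette records the
modelling decisions, their rationale, and what the validation does and does
not establish.

## The analysis chain

```{r}
library(rhizonet)
com  <- generate_counts(default_scenario(seed = 1))
rare <- rarefy(com$counts, seed = 2)                  # alpha diversity input
al   <- alpha_diversity(rare)                         # Shannon, Pielou, Chao1
ra   <- to_relative_abundance(com$counts)
pm   <- permanova(bray_curtis(ra), com$metadata$treatment, seed = 3)

smp  <- com$metadata$sample_id[com$metadata$crop == "maize" &
                               com$metadata$treatment == "coated"]
net  <- group_network(com$counts, smp)                # |rho| > 0.8, p < 0.05
part <- detect_modules(net, seed = 4)
rc   <- robustness_curve(net, seed = 5)
eg   <- module_eigengenes(ra[net$nodes, smp], part)
mt   <- correlate_modules(eg, com$metadata[match(smp,
          com$metadata$sample_id), ])
ko   <- knockout_experiment(com$counts, com$taxonomy, com$metadata,
                            "Trichoderma", samples = smp)
```

`run_pipeline()` executes the same chain from one configuration (an R list
or a YAML file; see `inst/extdata/demo_config.yaml`) and writes every stage
table plus a manifest with all resolved parameters. The numbered scripts
under `analysis/` are thin narrative drivers over the same functions.

## Network construction

Edges are pairwise Spearman associations between OTUs across the samples of
one (crop, treatment) group. Rho is tie-corrected (Pearson correlation of
average ranks). An edge requires `|rho| > 0.8` **and** `p < 0.05`, both
strict; p-values are raw by default (`p_adjust = TRUE` applies BH first).
Two-sided p-values come from the t approximation with `n - 2` degrees of
freedom, except for tie-free pairs at `n <= 9`, where the exact null
distribution of the rank statistic is enumerated (all `n!` permutations,
cached per `n`). At the study's own group size (`n = 6`) the smallest
attainable tie-free two-sided p is 1/360, and only `|rho| >= 0.886` passes
both thresholds, so single-group networks at this size are unavoidably
noise-dominated — roughly 3% of all null pairs qualify as edges. This is a
property of the design being emulated, not of the implementation, and it is
why the validation scenarios below use larger groups where an edge estimate
is informative.

Before correlation, taxa must appear in at least 3 samples of the group and
reach a mean relative abundance of 1e-4 (both configurable, both recorded in
the run manifest): rank correlations of near-constant vectors are
meaningless. All filtered taxa remain as network nodes even if edgeless, so
downstream set arithmetic (module matching) has a stable universe.

## Natural connectivity and robustness

Stability is summarised by natural connectivity,

$$\bar\lambda = \ln\!\Big(\tfrac1N \sum_{i=1}^{N} e^{\lambda_i}\Big),$$

with $\lambda_i$ the eigenvalues of the **binary** adjacency matrix of the
current (sub)graph and $N$ its current node count — the log-average closed-walk
weight, i.e. route redundancy. The binary convention follows the robustness
literature; a `weighted` flag uses $|\rho|$ instead. The sum is evaluated
with a log-sum-exp shift so large graphs cannot overflow. An empty graph
scores 0; both $K_3$ (`0.99631`) and $P_3$ (`0.57967`) closed forms, and
agreement with `ln(trace(expm(A))/N)` to 1e-8 on random graphs, are asserted
in the tests.

The robustness protocol removes `round(f * N)` uniformly random nodes
(half-away-from-zero rounding, making curves bit-reproducible under a seed)
for each fraction `f` on a grid spanning 0.01–0.60, recomputes natural
connectivity on the induced subgraph, and averages over `n_reps` removals.
The trapezoidal area under the mean curve (`robustness_auc()`) is the
one-number group comparison.

## Modules and their eigengenes

Module detection runs on the unsigned edge set with $|\rho|$ weights.  The
default algorithm is the map equation (Infomap). Greedy modularity
agglomeration was evaluated first and is still available
(`algorithm = "fast_greedy"`), but modularity maximisation has a known
tendency to fragment a single dense quasi-clique when only part of its
internal edges survive sampling — exactly the regime of a planted module at
`n = 30` — and in that regime it repeatedly split the planted module across
two or three labelled modules while Infomap kept it whole; the shipped
default is held to precision and recall of at least 0.9 by the
membership-recovery test. Modules
smaller than `min_module_size = 5` stay unlabelled. Module ids are ordinals
(by decreasing size); module *identity* across runs is always resolved by
content, e.g. "the module containing the focal genus", never by number.

The eigengene of a module is the first principal-component score vector of
its members' standardised abundance profiles: one activity value per sample.
Profiles are log-transformed first, with a per-taxon pseudocount of half the
taxon's smallest positive relative abundance. The log matters twice: it
linearises the multiplicative abundance model (without it, recovery of a
generating eigengene–trait correlation is biased downward because the
exponential upper tail dominates the PC), and it makes the eigengene exactly
invariant to rescaling any taxon by a positive constant. The sign is
oriented so the eigengene correlates positively with the module's mean
standardised abundance; the fraction of variance explained by the first
component is reported alongside.

Eigengene–variable association uses Pearson correlation (the convention of
the eigengene framework; Spearman by flag), two-sided p-values, pairwise
deletion of missing trait values, and one BH adjustment across the whole
module × variable matrix — both raw and adjusted p are emitted.

Hubs are nodes in the top decile (configurable `top_fraction`) of the whole
network by **both** degree and normalised shortest-path betweenness; tied
values keep all tied nodes, so a perfectly symmetric cycle flags everyone
rather than an arbitrary subset.

## The knockout experiment

The focal-genus dependence test mirrors the in-silico experiment of the
study: locate the baseline module containing most focal-genus OTUs, perturb
the count table, rebuild the network on the same samples with identical
parameters and seed, re-detect modules, and measure
`|target ∩ best rebuilt module| / |target|` (target restricted to nodes
present in the rebuilt network; ties broken toward the smaller module id;
Jaccard reported alongside). Two perturbations:

* **remove** — drop all genus rows. The genus's own OTUs are excluded from
  the target before matching, so the question is whether the *companion*
  taxa stay together without it.
* **reduce** — scale the genus in coated samples by one common factor so its
  mean relative abundance matches the control group's, rounding to integer
  counts and never touching control samples. One common factor (rather than
  per-OTU matching) is the minimal intervention preserving within-genus
  composition.

The persistence verdict is `shared proportion >= 0.5` by default; published
module-pairing procedures give verdicts without fixing a universal cutoff,
so the threshold is explicit, configurable and reported. Hub overlap between
the original and best-matching rebuilt module is reported alongside the
verdict but deliberately not folded into it.

A structural caveat discovered during validation: **reduce mode is nearly
rank-preserving**. Scaling all coated samples of a genus by one constant
does not change the across-sample rank order of its counts, so Spearman
edges survive except through integer rounding at low counts and the small
renormalisation of other taxa. In the synthetic regime (ample depth) reduced
modules therefore persist; dissolution under abundance reduction, as a real
dataset may show, requires detection-floor effects (counts rounding to zero,
prevalence-filter dropout) that the generator's depths do not produce. The
remove mode, and the contrast with a sham knockout of an uninvolved genus,
carry the inferential weight here.

## Diversity statistics

Shannon (nats), Pielou (`H / ln S_obs`, defined as 1 for a single-taxon
sample) and bias-corrected Chao1 (`S_obs + F1(F1-1) / (2(F2+1))`, finite even
with no doubletons) are computed on rarefied counts; rarefaction is
without-replacement subsampling to a common depth (default: the minimum
sample total, since the emulated protocol normalises to an unstated depth),
seeded and zero-preserving. Group comparisons use the two-sided Wilcoxon
**rank-sum** test: the source protocol names the signed-rank test, but the
design compares independent treatment groups of (generally) unequal size,
for which the signed-rank statistic is undefined; a `paired` option exists
should a genuinely paired design arise. Exact p-values are used for small
tie-free samples, the tie-corrected normal approximation otherwise, and an
all-tied comparison returns p = 1 with a warning. BH correction is applied
across each comparison table. Beta diversity is Bray-Curtis on relative
abundances with PERMANOVA (adonis-style, 999 permutations by default,
`p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})`).

## The synthetic community generator

The generator is the package's ground-truth instrument. For each sample it
draws a latent log-abundance
$x_{is} = \mu_i + \sigma L_{is}$, converts to a composition by softmax, and
draws counts multinomially at a negative-binomial depth
(variance $\mu + \phi\mu^2$). The latent field $L$ carries the planted
structure:

* **Baselines** $\mu_i \sim N(0, 1)$; planted-module members instead get
  $N(-1, 0.3)$ and the focal OTUs a fixed low baseline. This keeps planted
  modules at a few percent of reads. The choice is load-bearing: because
  compositions close to 1, a module holding a dominant share drags the
  denominator with its own factor and attenuates the very correlations being
  planted, increasingly so as the module's read share grows.
* **Modules.** Members of an ordinary module share a factor
  $f_s \sim N(0,1)$ with $L = \sqrt{\lambda} f + \sqrt{1-\lambda}\,\epsilon$,
  so `loading` equals the member–member latent correlation. A *focal*
  module is star-shaped: the focal OTUs load at 0.97, companions at the
  module loading, and companion residuals get a slightly negative
  exchangeable correlation, pushing companion–companion association toward
  its feasibility floor. Positive-semidefiniteness makes that floor explicit:
  with $k$ companions each correlated $r$ with the focal factor, mutual
  correlations cannot fall below $(kr^2-1)/(k-1)$. For $r \approx 0.9$ and
  $k \ge 5$ that floor sits at the 0.8 edge threshold itself — so the
  knockout scenario uses 4 companions, the regime where "the module exists
  only through the focal genus" is geometrically realisable.
* **Coating effects.** Module factors can be restricted to coated groups;
  focal OTUs are multiplied by an enrichment factor (default 4) under
  coating; and `competition_strength` arranges non-module taxa into pairs
  whose latents correlate at `competition_cor` (default −0.95) only in
  coated samples.
* **Traits.** Each trait/enzyme is `baseline + c·f + N(0, sd)` with `f` the
  coupled module's factor (0 where inactive); with the default
  `sd = sqrt(1 - c^2)` the generating correlation is `c` itself, so the
  default scenario plants growth traits at +0.7/+0.8, enzymes at
  +0.75…+0.85 and disease incidence at −0.6 — the qualitative pattern the
  analysis is meant to detect.

One master seed drives everything; `split_seed(seed, label)` derives a
deterministic stream per stage, so fixtures are byte-reproducible and stages
are independently reseedable.

### Scenario presets and problem sizes

`default_scenario()` is the study emulation (200 OTUs, 2 crops × 2
treatments × 6 replicates, depth 2e4): it is what the pipeline, the
`analysis/` scripts and the diversity-neutrality checks run on. The
validation presets deliberately move to sizes where the estimated quantity
is informative, chosen once at design time: membership recovery at 30
samples/group and depth 1e5-ish signal margins (`recovery_scenario()`),
eigengene–trait recovery at n = 60 (`trait_scenario()`), negative-edge
direction at 15/group (`negative_edge_scenario()`), and the knockout at 50
coated samples (`knockout_scenario()`). At n = 6 these single-run
comparisons are noise-dominated (see above), which is itself faithful to the
emulated design.

### What the generator does not emulate

No phylogenetic signal, no sequencing-error or chimera artifacts, no
explicit ecological dynamics (negative couplings are correlational stand-ins
for competition, not Lotka–Volterra interactions), no taxon-specific
zero-inflation beyond what the multinomial produces, and depth jitter only
through the negative-binomial totals. One honest artifact is retained:
compositional closure alone produces some negative associations (control
networks in the competition scenario carry a modest negative-edge share
with no planted competition), so "negative edge" should be read as
*association*, not mechanism — which is equally true of the real analysis.
Consequently, green tests establish that the implementation detects the
structures it claims to detect under a known, favourable generative model;
they do not establish power or error rates on real rhizosphere data.

## Numerical and degenerate-input conventions

Strict inequalities at both edge thresholds (an exact 0.8 is not an edge).
Constant taxa are excluded from correlation with a warning, never silently.
All-zero samples are errors at normalisation, never silent zeros. An
edgeless network is returned with a warning and yields an all-unlabelled
partition; its negative-edge ratio is `NA`. Removal counts round half away
from zero. Matching against an empty rebuilt partition gives proportion 0.
An unknown genus warns and returns an empty member set. Eigengene modules
that collapse below two usable members are errors. The exact Spearman null
is enumerated only for `n <= 9` (`9! = 362,880` permutations, cached).

## Known limitations

Group networks at the emulated design's n = 6 are descriptive, not
inferential; the package reports them faithfully rather than pretending
otherwise. The shared-node matching rule and the 0.5 persistence cutoff are explicit,
reported choices standing in for pairing procedures that are described only
qualitatively in the literature. Reduce-mode knockouts are structurally conservative under
rank-based edges (see above). PERMANOVA assumes exchangeability under the
null; with strong dispersion differences between groups its p-value reflects
both location and dispersion.
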