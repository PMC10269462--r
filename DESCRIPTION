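Package: rhizonet
Title: Co-Occurrence Network Analysis of Rhizosphere Microbiomes Under
    Seed-Coating Inoculation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how a fungal seed-coating inoculant reshapes
    rhizosphere microbial community structure. Builds signed Spearman
    co-occurrence networks from OTU count tables (edge rule |rho| > 0.8,
    P < 0.05), compares negative-edge proportions between coated and
    control communities, quantifies network stability by natural
    connectivity under random node removal, summarises network modules by
    eigengenes and correlates them with plant traits and soil enzyme
    activities, identifies hub taxa by joint degree and betweenness, and
    tests whether a module depends on a focal genus by in-silico knockout
    (removal or abundance reduction) followed by network reconstruction
    and shared-node module matching. Ships a seeded synthetic community
    generator that emulates the two-crop, coated-versus-control pot
    design, plus alpha/beta diversity statistics (Shannon, Pielou, Chao1,
    Bray-Curtis, PERMANOVA) and rank-based group tests with
    Benjamini-Hochberg correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
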