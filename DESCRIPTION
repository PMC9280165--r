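Package: gxtissue
Title: Genotype-by-Tissue Interaction Analysis of Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-environment-trial statistics applied to tissue panels of
    qPCR relative expression (2^-ddCt): split-split-plot analysis of variance
    with its three error strata, AMMI (additive main effects and
    multiplicative interaction) decomposition of the gene-by-tissue table
    with Gollob F-tests for the interaction principal component axes, and
    GGE (genotype main effect plus genotype-by-environment interaction)
    biplot analysis with the which-won-where, mean-versus-stability,
    discriminating-ability and ideal-genotype views. All analyses can run
    from sufficient statistics (per-cell mean, SD, n), and a packaged
    summary dataset of four cold-resistance genes measured in nine tissues
    of Takifugu rubripes at four water temperatures is included, together
    with seeded generators for the corresponding split-split-plot and AMMI
    forward models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
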