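Package: syntroflux
Title: Community Flux Balance Analysis of Syntrophic Biogas-Upgrading Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble abundance-weighted community metabolic models
    from species-level constraint-based reconstructions and to simulate
    syntrophic carbon dioxide methanation. Implements medium construction
    from chemical recipes, conversion of reactor gas measurements into
    specific flux bounds, two-stage cooperative-tradeoff optimization of
    community growth, extraction and thresholding of cross-feeding exchange
    networks, finite-difference elasticity analysis of interventions on
    medium composition and species abundance, and a coverage-correlation
    co-occurrence screen for metagenome-assembled genomes. Ships a
    parameterized generator of toy anaerobic-digestion communities (one
    hydrogenotrophic methanogen, one versatile acetogen, one volatile fatty
    acid degrader and two fermenters) so that the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    quadprog,
    rlang,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
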