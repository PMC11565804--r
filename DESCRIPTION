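Package: g4kit
Title: RNA G-Quadruplex Binding and Ribonucleoprotein Condensate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for studies of protein binding to
    RNA G-quadruplexes (rG4) and the liquid-liquid phase transitions they
    drive. Implements bind-n-seq k-mer and G4-motif enrichment statistics,
    Hoogsteen hydrogen-bond and G-quartet detection in coordinate
    trajectories, protein-RNA condensate contact/multivalency/crowder
    analyses, GROMOS-style conformational clustering, mean-squared
    displacement and diffusion estimation, FRET efficiency-distance
    conversion, and nonlinear fits of one-site binding and one-phase
    association (FRAP) curves, together with synthetic-data generators that
    provide ground-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
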