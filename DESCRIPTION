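Package: roguestate
Title: Sensitivity of Parsimony Ancestral-State Reconstruction to Rogue-Taxon
    Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking how robust a parsimony ancestral-state
    reconstruction is to the placement of phylogenetically unstable ("rogue")
    taxa and to alternative codings of a morphological character.  Provides a
    unit-cost (Fitch-equivalent) parsimony engine on rooted, possibly
    polytomous trees that reports most-parsimonious-reconstruction (MPR) state
    sets at every node; tree surgery (prune/graft) for regrafting rogue
    terminals; systematic enumeration of a topology space built from backbone
    hypotheses crossed with all candidate rogue placements; and tidy summaries
    of reconstruction calls across that space.  Ships a worked exemplar around
    the evolution of carpel fusion (syncarpy) in flowering plants, where the
    ancestral gynoecium of the mesangiosperms and of the Ceratophyllum stem
    lineage is reconstructed over 96 alternative topologies under two codings
    of the fusion character.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
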