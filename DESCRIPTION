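Package: sisterdiv
Title: Speciation-Mode Classification for Sister Species in Sky-Island Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether sister species in island-like habitats
    (such as the Andean paramo) diverged by allopatric speciation or by
    parapatric ecological divergence. Extracts sister pairs (cherries) from an
    ultrametric chronogram, rasterises occurrence records onto decimal-degree
    grids to compute range overlap and asymmetry, assigns occurrences to
    habitat islands, tests leaf-area divergence between sisters with rank-sum
    tests, and applies a four-cell decision matrix to classify each speciation
    event. Also fits Pagel's lambda to species-mean log leaf area by profile
    maximum likelihood, and implements likelihood-based ancestral-range
    inference under DEC, DIVALIKE and BAYAREALIKE models with optional
    founder-event (+J) cladogenesis and AIC model selection. A synthetic-data
    module generates trees, island geographies, occurrences, leaf areas and
    range histories with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
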