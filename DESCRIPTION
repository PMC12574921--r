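Package: lisnet
Title: Iterative Protein-Protein Interaction Screening with AlphaFold-Multimer
    Interface Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines immunoprecipitation mass-spectrometry (IP-MS) candidate
    interactomes into high-confidence protein-protein interaction networks.
    Spectral-count tables are filtered by bait-versus-control fold change,
    AlphaFold-Multimer predicted aligned error (PAE) maps are scored with the
    Local Interaction Score (LIS) and Local Interaction Area (LIA), and a
    three-round iterative screen assigns retained preys to direct (Group 1),
    bridging (Group 2) and tertiary (Group 3) interactors around the bait.
    Also quantifies position-effect-variegation eye pigmentation from RGB
    images as background-corrected red-channel intensity with per-genotype
    fold changes. Ships synthetic-data generators with planted ground truth
    so every stage is testable without large-scale structure prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
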