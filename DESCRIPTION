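Package: ankprof
Title: Column-Wise Conservation, Variant and Structural Profiling of Ankyrin Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for column-wise analysis of tandem protein repeat families,
    developed around the 33-residue ankyrin repeat motif. Curates a repeat
    multiple sequence alignment by staged sequence-to-profile alignment with
    gap-introducer pruning and occupancy filtering; scores per-column
    evolutionary divergence (Shenkin score, normalised 0-100); aggregates human
    missense variants over alignment columns and computes missense enrichment
    scores (natural-log rate ratios with confidence intervals and Fisher
    p-values); summarises per-column structural features (relative solvent
    accessibility after Tien-style normalisation, eight-state secondary
    structure, beta-turn typing, Asx motifs); builds intra-repeat contact maps
    and contact/substrate-interaction enrichment scores; and combines
    divergence with enrichment into a conserved/unconserved x
    depleted/enriched position taxonomy with a concave/convex/basal surface
    classification. A synthetic-data module generates alignments, variant
    tables, structural tables and contact tables with known per-column ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
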