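Package: plasmaMorph
Title: Enrichment-Free Morphogenomic Profiling of Rare Plasma Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enrichment-free detection and morphogenomic
    characterization of rare plasma cells in blood and bone marrow.
    Classifies immunofluorescence-profiled single cells (CD138, CD56,
    CD45, DAPI) into plasma-cell morphotypes and enumerates them per mL,
    calls single-cell copy-number profiles from low-pass whole-genome
    bin counts with integer ploidy fitting and clone grouping, maps
    per-cell copy-number events onto a 12-event clinical FISH
    cytogenetics panel with discordance reporting, and provides exact
    rank-sum testing and cohort summary tables. Includes a seeded
    synthetic-data generator for immunofluorescence cohorts and
    single-cell bin-count profiles with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
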