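Package: tribcr
Title: Multi-Tissue B-Cell Receptor Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of immunoglobulin heavy-chain (IGH) repertoires sampled
    from several compartments of the same patient (tumor, draining lymph node,
    peripheral blood, normal tissue). Reads AIRR Rearrangement clonotype
    tables, removes cross-sample UMI contamination, applies UMI- and
    sample-level filters, and pools replicates by mean clonotype frequency.
    Computes repertoire overlap (F2, D, R) with per-isotype top-N
    normalization, clonality (1 - normalized Shannon-Wiener index), isotype
    composition, and CDR-H3 physicochemical profiles (charge, hydropathy,
    interaction strength, Kidera factors). Infers clonal lineages by
    V/J/CDR-H3-length partitioning with an automatic distance-to-nearest
    identity threshold, builds germline-outgroup-rooted trees, and derives
    hypermutation loads, distance-to-root ranks and Nei-Gojobori dN/dS.
    Provides triangle (barycentric) tissue-distribution statistics for clonal
    groups, exact-test detection of expanded clonotypes from UMI-normalized
    pseudo-counts, and a synthetic multi-patient repertoire generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
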