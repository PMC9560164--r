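Package: cellfatesim
Title: Cell-Fate Simulation and Lineage Analytics for Single-Cell Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cell-lineage databases produced by long-term
    single-cell tracking of cultured cells, and for agent-based cell-fate
    simulation driven by empirical event histograms ("Operation data").
    Provides the lineage data model with validation and population
    accounting; extraction of interval and event-frequency histograms per
    start/end event class together with a recovery fraction; linear dose
    interpolation between two reference models; a five-mode Monte-Carlo
    simulator of virtual lineages (bipolar and multipolar division, cell
    death, sibling cell fusion, censoring, recovery of non-growing cells);
    lineage analytics (event counts and per-frame rates,
    reproductive-ability grouping, doubling times, multipolar-division
    tracebacks, in-silico removal of cell death, disk-kernel density maps,
    damage-response attribution); a ground-truth synthetic-lineage
    generator for testing; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    optparse,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
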