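Package: offsetgraph
Title: Offset-Based Coordinate Systems and Intervals on Sequence Graphs
Version: 0.1.0
Authors@R:
    person("Offsetgraph", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for defining offset-based coordinate systems on graph-based
    reference genomes and for representing genomic intervals on them. Provides
    a directed acyclic sequence-graph data model, hierarchical and sequential
    region-path partitionings with backward-compatible coordinate update
    mappings, unambiguous single-path interval notation (minimal and full
    forms), multipath intervals (critical-subpaths and fuzzy edit-distance
    forms), graph construction from assembly placement tables (simple,
    flank-trimmed and alignment-merged graphs), projection of transcript
    annotations onto graph coordinates, and categorization of alt-locus
    transcripts relative to their main-path counterparts. Includes a
    deterministic synthetic fixture generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
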