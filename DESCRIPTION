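Package: datadepot
Title: Content-Addressed Research Data Store with Metadata-Driven
    Filesystem Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Manages collections of multi-file research data units in a
    flat, content-addressed store annotated by a key-value metadata graph
    with provenance edges. Data units are projected on demand into
    user-defined directory hierarchies ("context trees") of links, so the
    same data can be browsed under any ordering of grouping attributes.
    Includes a watch-folder ingestion workflow that groups incoming files
    into candidate units, drives metadata assignment with pluggable
    processing hooks, an SWC neuron-morphology reader with summary
    statistics, a seeded synthetic multi-animal project generator for
    end-to-end testing, and a command-line interface with state and
    recent-changes reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    igraph,
    openssl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
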