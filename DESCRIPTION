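Package: qdesign
Title: Factor-Based Experimental Design for Multi-Omics Sample Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates multi-tier sample hierarchies for high-throughput
    biological experiments from declarative factor and replicate
    specifications. Models a three-tier experiment (biological entities,
    sample extracts, test samples), assigns project-scoped identifiers with
    a weighted checksum character, serializes factor metadata to a small
    XML schema and a condensed text form, reads and writes a one-sample-
    per-row TSV exchange format with edit/reupload merge semantics, and
    exports lab sample sheets and MaxQuant experimental-design files. A
    command-line interface binds the pieces into a non-interactive design
    wizard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    yaml,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
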