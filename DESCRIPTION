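Package: seedtrace
Title: Extended-Seed microRNA Binding-Site Discovery and Cross-Species
    Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microRNA binding sites in mRNA transcripts by
    enumerating complete and partial contiguous matches (minimum 6 bp) to an
    extended antisense seed sequence, classifies sites as conserved or
    non-conserved between ortholog transcripts by retention of position under
    optimal global pairwise alignment, designs wild-type/mutant inserts for
    dual-luciferase reporter assays, and quantifies luciferase, transwell
    chemotaxis, qPCR and clinical-score readouts with the normalizations and
    two-group test standard for such assays. A synthetic-data module
    generates ground-truthed transcripts with planted sites, diverged
    ortholog pairs and noisy assay tables so every stage is verifiable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    knitr
Config/testthat/edition: 3
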