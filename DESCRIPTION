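Package: rcalogic
Title: Repressor-Controlled Rolling Circle Amplification Logic Gates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico toolkit for Boolean logic gates built from
    allosterically regulated transcriptional repressors acting on circular
    rolling circle amplification (RCA) templates. Provides a threshold
    binding-rule model of inducer- and anti-inducer-regulated repressors,
    series/parallel composition of operator sites into gates, truth-table
    evaluation and gate classification, a propositional-calculus derivation
    engine over the four basic repressor modules, a compiler from target
    truth tables to template designs, a kinetic simulator of real-time RCA
    fluorescence with relative-RCA-rate quantification, and sequence-level
    template assembly with operator cross-occurrence screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
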