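Package: cmaplink
Title: Link Custom Compound Collections to SBML Disease Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Harmonizes compound identifiers (InChIKey, CAS registry number,
    PubChem CID, synonyms) across an application-specific compound collection,
    aggregates chemical-gene interaction tables exported in CTD-style and
    ChEMBL-style dialects, filters the interactions to the gene-like entities
    of an SBML/CellDesigner disease map, and materializes a bidirectional
    compound-to-gene / gene-to-compound JSON index. Query functions answer the
    three classic disease-map overlay questions: which map entities does a
    compound target, which targets do two compounds share, and which compounds
    hit a selected map entity, plus a whole-collection coverage summary. A
    synthetic fixture generator with planted ground truth makes the full
    pipeline testable without any network access, and a command-line interface
    wires the pipeline and queries into shell-usable subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    jsonlite,
    xml2,
    S4Vectors,
    IRanges,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
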