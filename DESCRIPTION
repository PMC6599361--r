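Package: ChemSparql
Title: Interoperable Chemical Structure Search over SPARQL
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale SPARQL endpoint for small-molecule datasets whose
    query engine recognizes chemical-search procedure calls encoded as
    ordinary triple patterns. Provides a molecular graph model with SMILES
    and MDL molfile readers, subgraph-isomorphism substructure and exact
    matching with configurable charge, isotope, stereo and tautomer
    semantics, Morgan-style connectivity fingerprints with Jaccard
    similarity scoring, a no-false-negative path-feature screening index,
    an in-memory RDF store with a SPARQL SELECT evaluator, the four W3C
    standard result serializations (XML, JSON, CSV, TSV), an HTTP endpoint
    speaking the SPARQL 1.1 protocol, and a deterministic synthetic
    fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    xml2,
    httpuv
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    curl,
    callr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
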