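Package: pathtrace
Title: Parsimony Reconstruction of Metabolic Pathway Evolution Across
    Pangenome Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the most parsimonious evolutionary history (presence,
    gain, loss) of metabolic pathways across a species or strain phylogeny.
    Enzyme-level homology counts from similarity-search tabular output are
    aggregated into fuzzy pathway profiles, discretized with a threshold
    alpha, and reconstructed bottom-up on the tree with GAIN/LOSS rules.
    Includes pangenome "virtual genome" handling, target-set diagnostics
    (matrix entropy and gradient-entropy segmentation), BioPAX Level 3
    pathway extraction and presence/absence annotation, and a seeded
    synthetic-ensemble generator with planted evolutionary histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
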