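Package: foodscreen
Title: Virtual Screening of Food Compound Libraries with Cumulative ADMET
    Scoring and Consensus Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An in-silico screening pipeline for food-derived compound
    libraries. Reads and curates compound tables (CSV, SDF, SMILES),
    applies a three-stage pre-filter cascade (chemical-class exclusion,
    inorganic/water removal, molecular-weight cut-off), computes the seven
    physicochemical descriptors used for drug-likeness filtering, scores
    compounds against a configurable rule set over descriptors and ADMET
    toxicity endpoint predictions with a cumulative score, ranks and
    selects top candidates, aggregates ranked target-prediction hit lists
    from multiple tools into consensus votes and a bipartite
    compound-target network, and provides the fluorescence-ratio and
    replicate statistics used to analyse the accompanying bioassays.
    A synthetic-data module generates libraries with planted rule-passing
    actives, simulated multi-tool target predictions, and assay readouts
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
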