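Package: hergsuite
Title: Curation, QSAR Modeling and Interpretation of hERG Channel Blockade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An offline toolkit for building and interrogating fingerprint-based
    QSAR models of hERG potassium-channel blockade. Curates bioactivity tables
    (qualifier filtering, structure standardization, duplicate resolution) into
    binary, multiclass and regression datasets on the pIC50 scale; computes
    hashed circular (ECFP/FCFP) and MACCS fingerprints with bit-to-atom
    environment maps; trains and validates five learner families with
    stratified splits, cross-validation and Y-randomization; estimates a
    distance-based applicability domain; combines the three tasks into a
    weighted consensus blocker call; and explains predictions with
    Shapley-value bit attributions projected onto atoms. Includes a synthetic
    bioactivity generator with planted fingerprint signal so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml,
    xgboost,
    ranger,
    e1071,
    caret,
    pROC,
    kernlab,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'applicability.R'
    'chem.R'
    'chemspace.R'
    'consensus.R'
    'curation.R'
    'featurize.R'
    'fixtures.R'
    'hergsuite-package.R'
    'interpret.R'
    'modeling.R'
    'pipeline.R'
    'records_io.R'
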