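Package: troqsar
Title: Toxicity Rank Order Screening for QSAR Training Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the toxicity rank order (TRO), the base-10 log ratio of an
    acute endpoint (LC50) to a chronic endpoint (NOEC), classifies contaminant
    mode of action (narcosis, transition, reactive) by log-TRO thresholds, and
    uses the classification to screen QSAR training sets before fitting the
    two-dimensional baseline-toxicity regression of log LC50 on log Kow.
    Includes a curated organophosphate ester example dataset, CSV/JSON input
    and output, a labelled open-source log Kow estimator for SMILES input, and
    a synthetic-data generator for parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
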