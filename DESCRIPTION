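Package: diliwfp
Title: Bayesian Weighted Fingerprints for Drug-Induced Liver Injury Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-induced liver injury (DILI) from 881-bit PubChem
    structural fingerprints. Per-substructure class statistics with Laplace
    smoothing yield log2 odds ratios that weight fingerprint bits enriched in
    hepatotoxic compounds; classifiers (random forest on weighted features,
    support vector machine on a precomputed Tanimoto kernel) are trained,
    cross-validated over a grid of weighting parameters, and calibrated to a
    target sensitivity. Includes PaDEL-Descriptor CSV ingestion, structural
    alert reporting with PubChem bit annotations, a synthetic fingerprint
    generator with planted discriminative bits, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    kernlab,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
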