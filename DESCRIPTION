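Package: uaaScreen
Title: Virtual Screening of Unnatural Amino Acid Substitution Sites on Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting whether an unnatural amino acid (UAA) can be
    successfully incorporated at a given site of a protein by genetic code
    expansion. Computes per-site evolutional tolerance (alignment column
    entropy), steric descriptors (relative accessible surface area by the
    Shrake-Rupley method, half-sphere exposure, hydrogen-bond based secondary
    structure) and physiochemical change descriptors between the natural and
    unnatural amino acid; fits a ridge-penalized logistic model of the
    substitution outcome on a database of experimentally verified substitution
    records; provides holdout, balanced-resampling and date-based (timesplit)
    validation, ROC analysis with sensitivity+specificity cutoff optimization,
    a generalized linear model of incorporation efficiency, and full
    UAA-by-site probability matrices for screening candidate substitutions.
    Includes deterministic synthetic generators (ideal helices and sheets,
    simulated alignments, simulated substitution databases with known ground
    truth) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    bio3d,
    xml2,
    jsonlite,
    Biostrings,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    pROC,
    glmnet
Config/testthat/edition: 3
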