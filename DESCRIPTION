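Package: evstab
Title: Evolutionary Statistical Energy Ranking and Thermal Stability Analysis of Enzyme Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers Potts (direct coupling analysis) sequence models from
    multiple sequence alignments by regularized pseudo-likelihood
    maximization, scores and ranks single- and double-substitution enzyme
    variants by statistical energy differences, ingests structure-based
    ddG run tables, and quantifies thermal resistance from assay plates,
    two-state melting curves and first-order deactivation time courses.
    Includes synthetic-data generators with known ground truth for every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
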