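Package: lusurvey
Title: Discovery and Cross-Species Comparison of LU-Domain Three-Finger Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying LU-domain (Ly6/uPAR, "three-finger") proteins
    across taxa: profile hidden Markov model construction from a seed alignment
    and proteome scanning for LU-domain hits; global and local pairwise
    alignment with a Cys-Cys-upweighted BLOSUM62 matrix; the grouped-residue
    percent-similarity statistic and all-vs-all similarity matrices with a
    display-submatrix selection rule; a six-frame translated homologue survey
    over transcript assemblies with full-coverage filtering and best-hit-per-
    species selection; progressive multiple alignment, neighbor-joining
    dendrograms and Newick output; Hill-equation fits to ELISA dose-response
    data and dual-housekeeping qPCR normalization; plus seeded synthetic-data
    generators with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    minpack.lm,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
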