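Package: calgevo
Title: Ancestral Calgranulin Reconstruction Robustness and Biophysical
    Assay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for studying the evolution of
    calgranulin (S100A8/A9/A12/MRP126) innate-immune properties. Implements
    marginal ancestral sequence reconstruction on small trees under an
    equal-rates amino-acid model, construction of 'altAll' alternative
    ancestors from per-site posterior probabilities, exhaustive rooted-
    topology enumeration for clade-arrangement robustness checks, and Fitch
    parsimony mapping of binary traits. Also provides gel densitometry with
    flanking-background subtraction, global single-exponential proteolytic
    decay fitting, two-state equilibrium unfolding fits (linear extrapolation
    model), unfolding-kinetics fits, and normalization of antimicrobial
    growth-inhibition and NF-kB dual-luciferase reporter assays. A synthetic-
    data module generates every input class with known ground truth so the
    whole pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
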