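Package: abstab
Title: Antibody Germline Reversion and Biophysical Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for antibody stability engineering by germline
    reversion of rare somatic hypermutations (rSHM). Aligns variable domains to
    germline references, flags somatic hypermutations whose positional
    amino-acid frequency falls below a threshold, enumerates germline-reversion
    variant panels and applies a multi-attribute lead-selection funnel.
    Implements simulation and least-squares fitting of the biophysical assays
    used to rank variants: isothermal chemical denaturation (two- and
    three-state linear-extrapolation models), differential scanning calorimetry
    (non-two-state transitions), differential scanning fluorimetry (melting and
    aggregation-onset detection), 1:1 Langmuir binding kinetics for SPR/BLI
    including single-cycle designs and serum-interference ratios, and storage
    aggregation time courses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    signal,
    pracma,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
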