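Package: breakrec
Title: Recurrent Copy Number Breakpoint Detection and Gene-Level
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects chromosomal breakpoint locations from segmented DNA
    copy number profiles (array-CGH or low-pass whole-genome sequencing),
    maps breakpoint uncertainty intervals onto gene annotations, and
    identifies probes and genes recurrently affected by breakpoints
    across a tumor cohort.  Cohort-level recurrence is tested against
    exact Poisson-binomial null distributions computed via probability
    generating functions, with a linear-probability covariate correction
    for gene length, gene-associated feature count and per-sample
    breakpoint burden, and discreteness-aware (Tarone-Gilbert) false
    discovery rate control.  Includes a synthetic cohort generator with
    planted recurrent breakpoint genes for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
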