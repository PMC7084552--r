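Package: mitolac
Title: Mutation Profiling of Mitochondrial DNA by Chaos Game
    Representation and Fractal Lacunarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles mitochondrial genome mutation load from IUPAC-encoded
    sequence calls. Sequences containing heteroplasmic ambiguity codes and
    no-calls are mapped to Chaos Game Representation (CGR) matrices with
    fractional weighting of undetermined symbols, the matrices are
    sigmoid-regularized and scanned with the gliding-box lacunarity
    algorithm, and the lacunarity curve is summarized by a hyperbola model
    L(b) = beta/b^alpha + gamma whose beta parameter acts as a per-subject
    mutation-profile biomarker. Cohort-level tools compare the biomarker
    between two groups with normality-routed one- or two-tailed tests,
    exclude alpha outliers, and run randomized-split controls. A seeded
    synthetic-cohort generator emulates reference-plus-variant sequences
    at realistic homoplasmy, heteroplasmy and no-call burdens so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
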