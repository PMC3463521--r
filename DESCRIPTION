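Package: quadrivalent
Title: Reciprocal-Translocation Karyomorph Analysis for the Spiny Frog
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a reciprocal-translocation polymorphism in
    the Asian spiny frog (Quasipaa boulengeri): Levan-style karyotype
    classification from per-chromosome morphometrics with a 5S rDNA homology
    marker, the quadrivalent meiotic segregation model (alternate,
    adjacent-1, adjacent-2 modes) with offspring-karyomorph enumeration and
    viability-filtered crosses, deterministic and finite-population
    forward simulation of the single-migrant dispersal scenario,
    maximum-likelihood inference of gamete-pool frequencies from karyomorph
    count tables, the paired arm-length conservation test, and seeded
    synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
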