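Package: metawebr
Title: Build, Validate and Compare Species-Level Trophic Metawebs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to construct a species-level trophic metaweb from a
    taxonomic checklist and mixed-rank empirical interaction records.
    Implements rule-based taxonomic expansion of interaction records
    (genus-level expansion, habitat- and stratum-trimmed family-level
    expansion for generalist predator families and polylectic pollinators,
    and feeding-guild links), derivation of habitat and vertical-stratum
    associations from occurrence counts with threshold filters and
    median-share inference for data-poor species, diagnostics for truncated
    trophic chains (improper basal and apex positions, obligate cannibals)
    with special-case gap filling, binomial error-rate validation machinery
    (sample-size formula, Wilson score intervals, seeded sampling plans),
    and residual-based comparison of degree statistics across published
    metawebs. A synthetic-data generator with an independent brute-force
    expansion oracle makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
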