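Package: reglink
Title: Deterministic and Probabilistic Record Linkage of Administrative
    Registries with Linked-Versus-Unlinked Bias Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links person-level source extracts (immigration landings,
    death registrations) to a population registry when no shared unique
    identifier exists. Implements NYSIIS surname standardization,
    mutually exclusive and exhaustive blocking, an ordered cascade of
    deterministic exact-match passes followed by Fellegi-Sunter
    probabilistic passes with log-odds weights and EM estimation of
    agreement probabilities, rule-based review of grey-zone pairs using
    postal-code-derived geography, one-to-one enforcement and
    source-file deduplication, and an evaluation layer computing linkage
    rates, method mix, standardized differences between linked and
    unlinked records, and precision and recall against ground truth.
    Ships a seeded synthetic-registry generator with realistic field
    corruption (typos, phonetic-equivalent misspellings, day/month
    transposition, missingness, era-dependent quality, skewed surnames)
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
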