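Package: codelistr
Title: Automated Construction, Validation and Review Auditing of Clinical Codelists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds clinical codelists (SNOMED CT code sets) from baseline
    codelists with minimal manual effort. Harmonises condition names across
    sources, maps legacy ontologies (Read v2, CTV3, Medcode) to SNOMED CT via
    TRUD-style mapping tables, generates draft code sets by keyword search,
    applies clinician keep/group/split directives, automatically validates
    ("shrinks") draft codes against trusted phenotype libraries such as
    CALIBER, and manages the residual two-reviewer clinical review with
    boundary-code adjudication and an append-only audit log. Ships a synthetic
    fixture generator so every pipeline stage is testable without access to
    clinical terminology releases, and a phase-oriented pipeline runner with
    checksum manifests for reproducible codelist releases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
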