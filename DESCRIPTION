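Package: ptewater
Title: Contamination Indices and Probabilistic Health Risk Assessment for
    Potentially Toxic Elements in Drinking Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment of potentially toxic elements (PTEs such as Pb, Hg,
    Mn and Fe) in drinking-water monitoring campaigns: contamination factors,
    degree of contamination and the heavy-metal pollution index (HPI) with
    their classification bands; deterministic ingestion health risk (chronic
    daily intake, hazard quotient, hazard index and carcinogenic risk) for
    child and adult receptors; Monte Carlo uncertainty propagation with
    rank-correlation contribution-to-variance sensitivity analysis; seasonal
    difference testing and Spearman correlation screening; and a seeded
    synthetic-sample generator emulating a two-season tap-water survey so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nortest,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
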