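Package: cliniclist
Title: Generate a Verified Region-Wide List of Primary Care Clinics from
    Physician Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, auditable pipeline that converts a physician
    license-registry table into a region-wide list of primary care clinic
    addresses. Registry rows are filtered to family physicians practising in
    the target province, practice addresses are canonicalized and collapsed
    into unique-address groups, authoritative partial facility lists
    (walk-in clinics, urgent and primary care centres, hospitals,
    corrections and long-term care facilities) are joined by canonical
    address key, and a small term-expression language compiles named
    inclusion and exclusion criteria that sort every unique address into
    exactly one working list. Every address ends up included, excluded, or
    undetermined, with a per-stage audit trail, flow-count conservation
    checks, geographic enrichment via an offline geocode cache and
    community-health-area lookup, descriptive summaries by rurality class,
    and a seeded sampling workflow for manual verification with an accuracy
    statistic and re-ingestion of prior verification rounds. A synthetic
    registry generator with gold labels makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
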