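# cliniclist

Many health regions have no reliable list of the places where primary care
is actually delivered. Physician license registries enumerate *people* —
every registered physician, with the practice addresses they declared —
but not *clinics*, and a growing share of registered family physicians
work at hospitals, long-term care homes, administrative offices or other
sites where no community patient can book an appointment. `cliniclist`
turns a license-registry table into an auditable, region-wide list of
primary care clinic addresses, for health-services researchers and
planners who need the clinic — not the individual physician — as the unit
of analysis.

## The algorithm

The pipeline is deterministic and rule-based, with an audit trail at every
step:

1. **Filter physicians.** Keep registrants whose specialty labels match a
   family-practice term list; keep only practice addresses in the target
   province (postal-prefix fallback for blank province fields, flagged).
2. **Canonicalize addresses.** Case folding, punctuation stripping,
   street-type abbreviation expansion (`St → Street`, `Blvd → Boulevard`,
   ...), unit/suite extraction, postal-code normalization, PO-box
   flagging. Each address becomes a deterministic *canonical key*; the
   physician-centric table collapses into unique-address groups carrying
   every physician registered there. Exact-key matching only — lookalike
   keys go to a human-review report, never an auto-merge.
3. **Partition into working lists.** Every unique address is assigned to
   exactly one named working list by a three-stage cascade:
   - *partial lists*: authoritative facility lists (walk-in clinics,
     urgent and primary care centres, hospitals, corrections, long-term
     care) joined by canonical key — first match in configured order wins,
     conflicts logged;
   - *term criteria*: named inclusion/exclusion matchers compiled from a
     small term-expression language
     (`Wom[a,e]n* or Menopause or Matern*`, `Family and (Med* or Clinic
     or ...)`) where `*` is a token-prefix wildcard, `[a,e]` a one-letter
     class, and `[-]` an optional hyphen; exclusions run before
     inclusions by default;
   - *count fallback*: unmatched addresses with ≥ 2 physicians are
     multi-practitioner (included), with exactly 1 single-practitioner
     (undetermined, pending verification).
4. **Enrich and consolidate.** Offline geocode cache + community health
   service area lookup attach coordinates and a seven-class rurality
   label; working lists merge into included / excluded / undetermined
   buckets with conservation checks (address counts and physician-address
   pairing counts are asserted to be conserved on every run).
5. **Verify and iterate.** A seeded sampler draws per-list verification
   samples for manual review; recorded outcomes yield a per-list accuracy
   statistic (share of sampled addresses whose verified status agrees
   with the list's disposition) and feed back into the next run, moving
   addresses between buckets with a logged audit trail.

A synthetic registry generator with gold labels (`generator_config()`,
`generate_synthetic_data()`) makes the whole pipeline testable with no
external data.

## Worked example

Simulate a small study area and run the pipeline end to end:

```r
library(cliniclist)
cfg <- cla_simulate("demo", generator_config(seed = 2026, n_clinics = 50))
res <- cla_run(cfg)
```

The run log mirrors the stage flow (input / assigned / remaining), e.g.:

```
FP filter: kept 232 of 262 physicians (dropped 30)
Province filter: removed 8 addresses; dropped 4 physicians
75 unique addresses from 244 physician-address pairings
  partial_list:walk_in             in=75 assigned=4 remaining=71
  ...
  term:clinic_center               in=45 assigned=11 remaining=34
  count_fallback:multi_practitioner in=34 assigned=9 remaining=25
  count_fallback:single_practitioner in=25 assigned=25 remaining=0
```

Of the 262 simulated physicians, 232 matched the family-practice filter;
their in-province addresses collapse to 75 unique addresses, each sorted
into exactly one working list. Consolidation and the geographic summary:

```r
res$final
#> Final clinic list: 33 included / 17 excluded / 25 undetermined of 75 unique addresses
geo_summary(res$final)[, 1:5]
#>       rurality unique_address_n unique_address_pct fp_assignment_n median_fp
#> 1 metropolitan                8              24.24              18       2.5
#> 2  large_urban                8              24.24              26       3.5
#> ...
#> 7        Total               33             100.00             164       3.0
```

33 addresses qualify as primary care clinics, 17 are excluded (hospitals,
long-term care, administrative sites, ...), and 25 single-practitioner
addresses await manual verification. Percentages are computed half-up to
two decimals via `cla_percentage()` (e.g. `cla_percentage(6942, 13726)`
is `50.58`), and per-address physician counts are summarized as median,
type-7 interquartile range and range via `median_iqr_range()`.

`cfg$out_dir` then holds `final_clinics.csv`, one CSV per working list,
`flow_report.csv`, `summary.csv`, `verification_sample.csv`, side reports
(unjoined facilities, stage-1 conflicts, near-duplicate keys) and
`run_metadata.yaml` with the seed and input checksums. A thin CLI wrapper
lives at `inst/cli/cla.R` (`Rscript cla.R run --config config.yaml`).

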