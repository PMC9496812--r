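---
title: "Deriving a primary care clinic list from physician registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a primary care clinic list from physician registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliniclist)
```

## The problem and the model

A physician license registry is a table of people: every registered
physician, their declared specialties, and one or more practice
addresses. A clinic list is a table of places. The gap between the two is
not just aggregation — many registered family physicians list addresses
where no community patient can receive primary care (hospitals,
long-term care facilities, corrections facilities, administrative
offices, virtual-care headquarters), and one clinic appears in the
registry as many inconsistently spelled address strings.

`cliniclist` models the conversion as a deterministic classification of
*unique addresses*. The unit of analysis is the `AddressGroup`: one
canonical address together with all physicians registered there. Every
group is assigned to exactly one *working list*, and every working list
has a fixed *disposition*:

* **included** — walk-in clinic, urgent and primary care centre, family,
  first-nations, clinic/centre, multi-practitioner;
* **excluded** — hospital, long-term care, corrections, sexual health,
  women's health, virtual, administrative;
* **undetermined** — single-practitioner (a lone physician at an
  unlabeled address: could be a solo clinic, could be a residence;
  only manual verification can tell).

That is fourteen working lists: the twelve named criteria plus the two
count-fallback lists. `partition_config(extra_lists =)` leaves a slot for
additional custom lists for teams whose region needs more categories.

Two modelling assumptions matter. First, physicians are assumed to
register every address where they provide care; where that fails, clinics
are undercounted — this is a property of the source data the pipeline
cannot repair. Second, facility identity is equated with canonical
address equality: two suites in one building are two candidate clinics,
and one clinic spread over two street entrances is two groups unless a
manual override merges them.

## Stage order and why it matters

Assignment is a first-match-wins cascade:

1. **Partial lists** (walk-in, urgent and primary care, hospital,
   corrections, long-term care, in that order) joined by exact canonical
   key. Authoritative lists outrank any text matching: an address on the
   hospital list that happens to carry "Family Medical Clinic" in its
   label is a hospital. Entries matching more than one list are resolved
   by the configured order and logged as conflicts, never silently
   resolved.
2. **Term criteria**, by default every *exclusion* criterion before any
   *inclusion* criterion. This is the conservative choice for a clinic
   list: an address that reads like both a women's-health program and a
   family practice ("Women's Family Clinic") should not inflate the
   clinic count. The order is fully configurable and recorded in run
   metadata; both orders are exercised in the test suite, and the
   sensitivity is confined to labels matching both an inclusion and an
   exclusion vocabulary.
3. **Count fallback** for everything else: two or more physicians at an
   unmatched address is de facto group practice (included); exactly one
   is undetermined.

The term language itself is small: `*` allows any trailing characters on
a token, `[a,e]` is a one-character class, round brackets group
`or`-alternatives under `and`. Matching is case-insensitive, apostrophes
are stripped first (so `Wom[a,e]n*` fires on "Women's"), and every atom
must start at a token boundary — plain substring matching would fire
"Care" inside "Scared". A trailing `*` removes only the end-of-token
requirement. `[-]` (as in `E[-]Health`) is read as an *optional hyphen*,
matching both "EHealth" and "E-Health": reading it as a one-character
class would make the bracket pointless, so the non-degenerate
interpretation is the default and a strict mode matches the hyphen
literally. Criteria are evaluated against the concatenation of the
embedded facility label and the street lines only; city and postal code
are excluded because place names ("Hospital Creek") would misfire.

The notorious vocabulary collision is documented rather than patched:
`Hosp*` catches "Hospice House". Hospices that appear on no facility list
are excluded as hospitals. This is why list-based exclusion precedes term
matching, and why the audit trail records every fired atom per address.

## Address canonicalization

The canonical key is built from: case folding; apostrophe and punctuation
stripping; whitespace collapse; expansion of a configurable street-type
abbreviation table; extraction of unit/suite designations (`Suite 200 –`,
`#200`, `200-1234 Main`) into a dedicated key slot; postal-code
normalization to `A1A 1A1`; PO-box flagging. Keys are matched exactly.
Three deliberate choices:

* **Units are kept in the key** (default `keep_units = TRUE`): merging
  across suites would fuse genuinely distinct clinics in medical
  buildings. The choice is configurable, and a near-duplicate report
  (normalized edit similarity above a threshold, default 0.9) surfaces
  candidate merges for humans.
* **No fuzzy auto-merge, ever.** Similarity output is advisory.
* **Postal codes never merge on their own** — one postal code covers many
  buildings.

Degenerate inputs: an address with empty street, city and postal code is
an error at normalization but physicians with *no* address at all are
routed to an unaddressed report, because license registries are dirty and
a crash per dirty row would make the tool unusable. PO boxes are flagged
and left to the manual-override file (a two-column raw-key → replacement
CSV applied before grouping), mirroring how such addresses must be fixed
by hand before geocoding.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `fp_terms` | `"family"` (case-insensitive substring) | registries vary in label vocabulary ("Family Medicine", "Family Practice"); the substring is the robust common core |
| `province_code`, `postal_prefix` | `"BC"`, `"V"` | blank province fields fall back to the postal prefix and are flagged for review rather than dropped |
| partial-list order | walk-in, upcc, hospital, corrections, long-term care | fixed, logged; conflicts between lists are rare and logged either way |
| `term_order` | exclusions before inclusions | conservative toward the clinic list; fully configurable |
| `keep_units` | `TRUE` | suites are distinct candidate clinics |
| quartile method | type-7 linear interpolation | integer-looking reported IQRs do not identify the method; one method is fixed and documented |
| percentage rounding | half-up, 2 decimals (1 for accuracy) | matches the convention of the reported ratios |
| sample-size rounding | `nearest` (also `floor`/`ceiling`) | a stated 15.98 % of 1320 corresponds to 211 drawn under nearest rounding and 210 under floor; nearest reproduces the reported count |
| verification proportions | 0 for government-sourced lists; 0.27 family; 0.1598 single-practitioner; 1 otherwise | government lists are assumed accurate; the two stated coverages are adopted; remaining defaults are placeholders a study team should set deliberately |

All randomness (verification sampling, synthetic generation) flows from a
single integer seed carried in the run config and echoed into run
metadata, so a run is reproducible from its config and inputs alone;
outputs are byte-identical across re-runs (run metadata omits timestamps
by default for exactly this reason).

## Geographic enrichment

Geocoding is a pluggable resolver contract: one address string in,
coordinates plus a community-health-service-area id out, or
"unresolved". Offline runs use only a cache CSV keyed by canonical key,
making CI fully network-free; resolver exceptions (e.g. network faults)
degrade to "unresolved" and never abort a run. Rurality is a seven-class
closed vocabulary (metropolitan → remote) attached via the area lookup
table. Because more than one reasonable urban/rural dichotomization of
seven classes exists, `urban_dichotomies()` reports two candidate cuts
(top four classes; top four plus rural hub) side by side and labels
neither authoritative.

## Verification support

The package samples, records and scores manual verification; it performs
none. Per working list, a seeded uniform draw without replacement selects
`proportion × n` addresses. Accuracy is the share of sampled addresses
whose recorded outcome agrees with the list's disposition; "unknown"
outcomes stay in the denominator by default (conservative), configurable.
Prior-round records re-attach by canonical key on re-runs; records whose
address vanished are reported as orphans. Outcome-driven moves during
consolidation are asymmetric by design: a verified
"does not provide primary care" expels an address from any bucket,
while "provides primary care" only promotes *undetermined* addresses —
it never overrides a rule-based exclusion, which would need an explicit
override instead.

## What the generator emulates — and what it does not

`generate_synthetic_data()` plants a study area with known truth: clinics
per category with vocabulary-bearing names, physicians-per-clinic drawn
from a long-tailed distribution (mass at 2, quartiles 2 and 4, tail to
23), solo physicians, non-family physicians, multi-address physicians,
out-of-province addresses, facilities absent from the registry, and four
independently toggleable families of address-surface noise (case,
abbreviation, suite format, punctuation). Gold labels cover every planted
address and are written to a CSV the pipeline never reads.

It does **not** emulate: geographic realism of any region, realistic
workforce sizes, misspellings beyond the four noise families (no
character-level typos), nurse-practitioner-led clinics (absent from a
physician registry by construction), or adversarial name vocabulary
outside `adversarial_cases()`. Passing the gold-recovery tests therefore
shows that the pipeline's stages are individually and jointly correct
under controlled variation — not that real registry data contains no
surprises. Problem sizes used by the test suite and acceptance script —
10–60 clinics for unit and property tests, 200 clinics for the gold-label
recovery check, 10^4 randomized trials for the term-engine oracle — were
chosen as the sizes at which every structural feature of the generator
(all categories populated, multi-address and multi-physician overlap,
every rurality class) is present.

## Known limitations

* A physician who does not register a practice address hides that clinic
  entirely; the tool cannot see what the registry does not record.
* `St` always expands to `Street`, so "St. Paul Ave" canonicalizes
  imperfectly; the near-duplicate report is the safety net.
* Exact-key matching means an unrecognized abbreviation creates a
  spurious extra group rather than a wrong merge (the conservative
  failure mode).
* Hospices without a facility-list entry are excluded by the hospital
  prefix term.
* The single-practitioner list is known to be nonspecific (residential
  addresses); its disposition is deliberately "undetermined", not
  "included".
* Verification proportions other than the two stated ones are
  placeholders, and verification itself is manual by definition.
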