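---
title: "Extracting PFT reports into a research data mart: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting PFT reports into a research data mart: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regexmart)
```

## The problem

Pulmonary function tests (PFTs) — spirometry, lung volumes, diffusion
capacity, pulse oximetry — are stored in many electronic health records as
machine-generated plain-text reports. The physiology inside them is discrete
and numeric, but locked in text: aggregating it for a research cohort
otherwise means manual chart abstraction, which is slow and introduces
transcription errors. Because the reports are machine-produced with a stable
layout, a small set of regular expressions can recover every value exactly.
`regexmart` implements that approach as a self-contained toolkit: a
declarative ruleset maps report text to a typed 107-field record; a batch
builder assembles records into a keyed wide table (a *data mart*); and a
validation workflow quantifies agreement between automated extraction and
(simulated) manual abstraction.

This is deliberately *not* natural-language processing. Regular expressions
are appropriate only for highly structured, machine-produced text; nothing
here generalizes to narrative clinical notes.

## The extraction model

A **ruleset** is an ordered list of rules over a declared field dictionary
(the schema). Each rule is a PCRE regular expression with named capture
groups; each group is bound to one schema field through a converter
(`decimal`, `integer`, `date`, `text`, `sex`). The contract:

* Rules are applied to the whole document independently of one another, in
  multiline mode (`^`/`$` anchor to line boundaries). The **first match in
  document order wins** — each report describes a single test instance, so
  multi-match semantics are not needed.
* Every schema field is produced by **exactly one** rule. A field bound
  twice is a load error; an unbound field is a lint error. One rule may
  produce several fields (a spirometry row rule binds six).
* A rule that does not match leaves all of its fields MISSING without
  failing the document. This is how the toolkit tolerates report components
  that were not administered: the section is simply absent, its rules do not
  match, and its fields are MISSING. Only the identity rule (MRN and exam
  date) is *required*; a document without an identity line cannot be keyed
  and is quarantined by the batch builder rather than silently dropped.
* A capture that fails conversion (non-numeric text in a numeric slot)
  demotes the whole rule to `conversion_error` with a warning — tolerant
  batch-ETL posture, never an abort.

Extraction is purely functional: the same (ruleset, document) pair always
produces an identical result, which is what makes rebuilds of the mart
reproducible cell-for-cell.

### Regex dialect

One dialect is fixed and documented: PCRE as compiled by base R
(`perl = TRUE`), named groups `(?<name>...)`, with `(?m)` prepended by the
engine. Decimal values use a period separator, an optional leading sign, and
no thousands separators — machine-generated output needs nothing more.
Dates in reports print as `MM/DD/YYYY` (US clinical convention); the `date`
converter parses exactly that format.

## The default PFT dictionary (a reconstruction)

The mart design this package reconstructs specifies *counts*, not field
names: 54 spirometry + 26 lung-volume + 12 diffusion + 2 pulse-oximetry +
2 anthropometric numeric measures, 6 patient and 5 measurement non-numeric
fields — 96 numeric, 107 total — plus 6 warehouse key columns. The shipped
dictionary names conventional PFT quantities that reconcile with every
count:

* **Spirometry**: 9 measures (FVC, FEV1, FEV1/FVC, FEF25–75, PEF, FEF50,
  FIVC, FIV1, MVV) × 6 columns (pre-bronchodilator value, % predicted,
  post-bronchodilator value, % predicted, % change, below-LLN flag) = 54.
* **Lung volumes**: 13 quantities (TLC, VC, FRC, RV, ERV, IC, RV/TLC, SVC,
  TGV, Raw, sGaw, VTG, He equilibration time) × (value, % predicted) = 26.
* **Diffusion**: 6 quantities (DLCO, hemoglobin-corrected DLCO, DL/VA, VA,
  IVC, Hb) × (value, % predicted) = 12.
* **Pulse oximetry**: SpO2 at rest and on exertion. **Anthropometrics**:
  height (cm), weight (kg).
* **Patient fields** (6): name, MRN, gender, race, ethnicity, patient type.
  **Measurement fields** (5): exam date, technician, ordering physician,
  notes, test quality.

Two placements were genuinely open and are package decisions: the MRN is
kept as a patient field in the dictionary *and* mirrored as the `mrn_key`
key column (identity must live in both places); and gender is a patient
field because the validation field set compares it. Ordering physician and
notes sit with the measurement fields to keep the patient category at six.
The dictionary is a reconstruction, not a byte-match of any vendor export,
and is fully swappable via the rule file (`inst/extdata/pft_default.rules`).

The 39 rules partition as: 1 identity (required) + 10 header/pulse-ox/notes
rules + 9 spirometry rows + 13 lung-volume rows + 6 diffusion rows.

Units are conventional PFT units (volumes L, DLCO mL/min/mmHg, height cm,
weight kg); the source description prints none.

## What the synthetic generator emulates

`generate_cohort()` stands in for a scleroderma-registry cohort whose
subjects undergo serial PFTs. Defaults are the study conditions:

| Parameter | Default | Why |
|---|---|---|
| tests per subject | 1–5, uniform | enables index-test selection among serial tests |
| exam/consent window | 2004-12-01 – 2010-09-30 | the validation study's test window |
| lung volumes administered | 90% of tests | components are not administered to every patient; no canonical rate exists, so a realistic one is fixed |
| diffusion administered | 85% of tests | same |
| sex | 80% female | scleroderma predominantly affects women |
| FVC | 1.0–5.5 L | documented generator range |
| TLC | 2.5–8.0 L | documented generator range |
| DLCO | 4–40 mL/min/mmHg | documented generator range |
| % predicted | 25–130 | documented generator range |

Every numeric truth value is drawn uniformly in its range and **rounded to
the precision at which reports print it** (volumes 2 decimals, ratios and
height/weight 1, percents integer). That makes ground truth and rendered
text informationally identical, so the round-trip property — extraction of a
rendered report equals its ground truth on all included fields, MISSING
exactly on omitted sections — is exact, not approximate.
Post-bronchodilator spirometry values are derived from the pre value and an
integer percent change so the printed row is internally consistent.

What the generator does **not** emulate: real vendor layout drift across
software versions, OCR noise, free-text idiosyncrasy, corrupted encodings,
or physiologic correlation structure between measures (values are
independent draws; a subject can print an implausible combination). Passing
tests therefore demonstrate correctness of the extraction machinery on
in-grammar documents, not robustness to out-of-grammar real-world reports —
on a real corpus the ruleset, not the engine, is what would need revision.

### The transcription-error plan

`simulate_manual_entry()` models the manual-abstraction arm: a copy of the
truth table corrupted at exactly the planned cells. Error kinds follow the
observed taxonomy of manual data entry: one-digit typos in identifiers and
values, date shifts, sex-code swaps. Magnitudes (±1–30 days, single-digit
substitution `d -> (d+1) mod 10`) are fixed to be realistic yet always
detectable — a substituted digit can never reproduce the original value, so
the Hamming distance between truth and manual table equals the plan size by
construction. The shipped `paper_error_plan()` pins six errors (2 MRN
typos, 2 date shifts, 1 height typo, 1 gender swap) to arbitrary distinct
subjects; the taxonomy fixes the error *types*, so which subjects carry them
is a free choice made once.

## The validation workflow

For each subject the **index test** is the one closest to the consent date;
equidistant ties go to the *earlier* test (no convention dictates the
tie-break; it only has to be deterministic and documented). `compare_tables()` then makes one
comparison per (subject, field) over the 11-field validation set — MRN,
exam date, gender, height, weight, FVC, FVC%, TLC, TLC%, DLCO, DLCO% — after
canonical normalization: ISO dates, numbers formatted at printed precision,
sex codes normalized. Comparison is **exact at rendered precision**: these
are transcriptions, not computations, so there is no tolerance to tune. Two
empty cells agree (a component correctly absent from both arms); a value
present on one side only is a `missing_cell` discrepancy; otherwise
discrepancies are classed by field kind (identifier / date / category /
numeric).

Numerical choices:

* `agreement_pct` rounds **half-up** to one decimal (1094/1100 → 99.5);
  base R's half-even rounding is not used for reported percentages.
* `double_entry_check()` passes when the discrepancy rate is strictly below
  the threshold (default 5%, the conventional ceiling for double data
  entry).
* Degenerate inputs: an empty document extracts to all-MISSING with zero
  errors; an empty cohort is valid; an empty comparison has `NA` agreement;
  selecting an index test from an empty list is an error.
* Surrogate keys (`patient_key`, `encounter_key`, `order_key`,
  `document_key`) are deterministic 8-hex-digit string hashes of MRN,
  (MRN, exam date) and document id — institutional warehouse keys are not
  reproducible outside the institution, and determinism is what the
  reproducibility guarantee needs. The hash is a simple 31-polynomial mod
  2^31−1: adequate for keying hundreds of documents, not cryptographic.
* MISSING exports as an **empty CSV cell**, never the string `"NA"`, for
  statistics-package friendliness.

This module reports exact agreement and classified discrepancies — the
quantity the validation actually printed — rather than correlation
coefficients; with error-free extraction against near-error-free manual
entry, correlations are uninformatively close to 1 and are out of scope.

## Problem sizes used by the shipped checks

The test suite and acceptance script run the full study at its native desk
scale: 100 subjects (≈300 rendered reports), two independent mart builds,
1100 cell comparisons; the reproducibility property is additionally checked
over 20 seeds at 6 subjects each, and round-trip recovery over 5 × 40
subjects (≥500 reports). These sizes were chosen as the smallest that
exercise every property at study scale; the whole suite runs in well under
a minute per scenario on a single CPU.

## Known limitations

* The field dictionary and the 39-rule partition are reconstructions
  matching the documented category counts, not any institution's original
  ruleset.
* The grammar is a single fixed layout; the engine supports arbitrary
  rulesets, but only one report family ships.
* No interpretation (obstruction/restriction classification), no database
  connectivity, no HL7 or EHR integration, no inferential statistics beyond
  agreement and rates.
* `value_kind = integer` values are stored as doubles in the mart (R has no
  typed integer need here; CSV round-trips are unaffected).
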