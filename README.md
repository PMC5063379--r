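# odmsim — semantic comparison of CDISC ODM study metadata

Medical documentation forms — case report forms, registry forms, routine
clinical documentation — are developed independently, revised over time and
rarely harmonised. Deciding whether two forms collect *the same thing* is a
prerequisite for secondary use of clinical data, for merging datasets and
for tracking form versions, but doing it by hand over hundreds of data
elements is impractical.

`odmsim` automates this for forms expressed as **CDISC ODM 1.3.1/1.3.2
study metadata** whose items are annotated with **UMLS concept codes**
(`Alias Context="UMLS"` elements). It is aimed at medical-informatics staff
who curate form repositories, prepare multicenter studies or screen routine
documentation for research reuse.

## The classification at the core

For each item the package derives

* the **concept domain** — the set of UMLS codes annotating the item
  (ISO/IEC 11179 usage), and
* the **value domain** — the item's data type plus its optional code list
  (each code-list entry again carrying a coded value and concept codes).

Every pair of annotated items is then assigned exactly one similarity level
by a cascade of gates, evaluated in order:

| level | meaning |
|---|---|
| `NOTCODED` | item has no concept codes; excluded from pairing, listed for manual review |
| `DIFFERENT` | concept domains differ |
| `SIMILAR` | concept domains equal, but the code-list concepts do not correspond or the item data types differ |
| `TRANSFORMABLE` | code-list concepts correspond entry-by-entry; stored data can be mapped back and forth |
| `MATCHING` | additionally the code-list data types and the coded values of corresponding entries are equal; data merges without transformation |
| `IDENTICAL` | additionally item names and code-list names are equal (case-insensitively) |

Code-list correspondence is decided on the *multiset* of per-entry concept
code sets, so duplicated entry signatures must occur equally often on both
sides; within one signature, entries are paired by ascending coded value.

On top of the classifier the package renders a short content summary
(items per group per form), a structural reference tree per file, per-level
pair listings, and a **comparable-items matrix** (rows = shared concepts,
columns = forms, one mark per occurrence — a form holding a concept twice
gets two marks). A deterministic synthetic-fixture generator with planted
relationships provides ground truth for end-to-end testing, and a small SUS
(System Usability Scale) module scores 10-item usability questionnaires
(odd items contribute rating−1, even items 5−rating, the sum × 2.5).

## Worked example

Generate the two-institution scenario (two oncology forms sharing eight
annotated concepts at mixed similarity levels), compare and build the
matrix:

```r
library(odmsim)

dir <- file.path(tempdir(), "demo")
gen <- synth_generate(synth_preset("cross_institution"), dir)
docs <- lapply(gen$files, read_odm)

res <- compare_all(docs)
print(res)
#> <ODM comparison: 18 item occurrence(s), 18 coded, 0 not coded, 153 pair(s)>
#>   IDENTICAL     3
#>   MATCHING      3
#>   TRANSFORMABLE 1
#>   SIMILAR       1
#>   DIFFERENT     145
```

18 item occurrences give C(18,2) = 153 pairs. Eight pairs sit at level
SIMILAR or above — the eight concepts the two hospitals share; the
remaining 145 pairs connect unrelated concepts. The matrix condenses this:

```r
m <- build_matrix(res)
print(m)
#> <comparable-items matrix: 8 concept group(s) x 2 form(s), min level SIMILAR>
#> (rows Active Surveillance, Analgesics, Tumour Board Type, Irradiation,
#>  Chemotherapy, Diagnosis, Birthdate, Hormone Therapy; every cell 1)
```

Each of the eight rows marks both forms once: every shared concept occurs
exactly once per hospital, so data exchange is possible for all eight —
directly for the `MATCHING`/`IDENTICAL` ones, after value recoding for the
`TRANSFORMABLE` one, and only after content review for the `SIMILAR` one
(same concept, incompatible value domain). `export_report()` writes all
sections as CSV/TSV or a standalone HTML page.

The same workflow is available from a shell via the installed
`inst/scripts/odmsim` wrapper:

```sh
odmsim compare form_a.xml form_b.xml --min-level matching --format csv --out report/
odmsim validate form_a.xml
odmsim sus ratings.csv
```

A batch containing a syntactically invalid file aborts with exit status 2
and validation messages on stderr (use `--force` to compare the valid files
only).

## Scoring usability questionnaires

```r
s <- sus_summary(sus_evaluation_data())
print(s)
#> SUS summary of 12 response(s): mean 74.2, min 40.0, max 97.5
#> per-respondent scores: 87.5, 82.5, 97.5, 80.0, 65.0, 80.0, 90.0, 40.0,
#>   45.0, 80.0, 75.0, 67.5
```

`sus_evaluation_data()` returns the bundled 12-participant evaluation of
the form-comparison workflow; a mean of 74.2 is conventionally read as good
usability.

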