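---
title: "Comparing semantically annotated ODM forms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing semantically annotated ODM forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odmsim)
```

## The problem and the model

Clinical documentation forms described in CDISC ODM carry, per item, a
name, an ODM data type, an optional code list, and — when semantically
annotated — UMLS concept codes attached as `Alias Context="UMLS"`
elements. `odmsim` treats each item as a pair of domains:

* **concept domain** — the *set* of concept codes on the item. Set
  semantics are deliberate: annotation order carries no meaning and
  duplicated codes add no information. An empty set means "not coded".
* **value domain** — the data type together with the resolved code list
  (whose entries have their own coded values and concept sets).

Pairwise similarity is decided by a cascade in which the first failing
gate fixes the level:

1. unequal concept domains → `DIFFERENT`;
2. code-list concepts not corresponding, or item data types unequal →
   `SIMILAR`;
3. otherwise at least `TRANSFORMABLE`;
4. plus equal code-list data types and equal coded values of
   corresponding entries → `MATCHING`;
5. plus case-insensitively equal item names and code-list names →
   `IDENTICAL`.

Items without codes are `NOTCODED` and never enter the pairing; they are
reported separately for manual review. The all-pairs driver resolves
every item *occurrence* across every (file, study, metadata version,
form) — a form referencing one ItemDef twice contributes two occurrences,
and multiple forms or metadata versions in one file are all distinct
sources.

### Design choices in the cascade

Several points are underdetermined by a prose description of such a
cascade; the package fixes them as follows and tests them explicitly.

* **Where the item data-type check lives.** The item data type is tested
  at the `SIMILAR` gate. Placing it later would let items with equal
  concepts but incompatible types reach `TRANSFORMABLE`, which would
  contradict the meaning of that level (data mappable back and forth);
  placing it at the `SIMILAR` gate makes the `MATCHING` requirement
  "item data types equal" automatically true — the only ordering
  consistent with both level definitions.
* **Multiset, not set, correspondence.** Code lists "fit" iff the
  multiset of per-entry concept-code sets is identical on both sides.
  Set equality would accept a two-entry list against a three-entry list
  with a duplicated signature, for which no entry bijection exists; the
  bijection is what makes value comparison at gate 4 well-defined.
* **Tie-break inside one signature.** When several entries share a
  concept signature, they are paired by ascending coded value. Any
  deterministic, order-independent rule works; ascending value is the
  simplest. For `MATCHING` the choice is immaterial (values must agree
  anyway), and correspondence itself never depends on it.
* **Normalisation.** Codes and coded values are identifiers: compared
  case-sensitively after trimming surrounding whitespace. Names are
  prose-like labels: compared case-insensitively after trimming, with
  internal whitespace significant. `float` and `double` are distinct ODM
  tokens and are never conflated.
* **Entries without concept codes** participate with the empty signature;
  two empty signatures correspond. This keeps correspondence total
  instead of making an un-annotated entry poison the whole list.
* **Grouping for the matrix.** Rows group items by *exact* concept-domain
  equality. Since every pair at `SIMILAR` or above has equal concept
  domains, this relation is transitive and the matrix is unambiguous —
  grouping by "any comparable pair" would not be.

## Parsing and validation

Parsing (via `xml2`) accepts the ODM namespace whether default or
prefixed, preserves document order, and ignores elements outside the
consumed subset (`ClinicalData`, administrative data, measurement
units). A declared `ODMVersion` other than 1.3.1/1.3.2 produces a warning
and a best-effort parse rather than a refusal — exports in the wild
frequently declare adjacent versions.

`validate_odm()` never raises; it returns a report. The built-in
structural check enforces what the comparison actually needs: required
`OID`/`Name`/`DataType` attributes, unique OIDs and coded values, and
resolvable references. The official CDISC XSDs are not redistributable,
so grammar validation runs only when the user supplies a schema path; a
small hand-written *synthetic* subset schema ships under `inst/extdata/`
to exercise that code path. A batch with any syntactically incorrect file
aborts the comparison (CLI exit status 2); `--force` compares the valid
remainder.

The package writes ODM only for its own fixtures. The emitter uses fixed
attribute order and indentation so that generated files are byte-stable,
which turns "same seed, same bytes" into a testable property and makes
`read_odm(write_odm(doc))` an exact round-trip on the consumed subset.

## The synthetic-fixture generator

No public corpus of UMLS-annotated ODM form sets can be shipped, so the
test bed is generated. A layout (`synth_spec()`) plants items with a
declared relationship to an anchor item in an earlier form; generation
derives the planted item from the anchor by the *minimal* edit that
forces the level:

* `IDENTICAL` — faithful copy (fresh OIDs);
* `MATCHING` — copy with a different item name;
* `TRANSFORMABLE` — copy with shifted coded values (entry concepts kept);
* `SIMILAR` — one entry's concept replaced (or, for list-free anchors,
  the data type changed);
* `DIFFERENT` — fresh concept code;
* `NOTCODED` — no annotation.

Unachievable layouts (e.g. `TRANSFORMABLE` against a list-free anchor, or
`IDENTICAL` with an explicitly different name) are rejected before
emission. Synthetic concept codes are UMLS-shaped (`C` + 7 digits) and
drawn without replacement from a seeded pool, so unrelated items can
never collide on a code; the classifier only ever tests code equality,
so real CUIs are unnecessary. Three presets reproduce the canonical use
cases at small scale (≤ 4 forms): version tracking (an item identical in
versions 1–3 and absent in 4; another whose code list changes between
versions, i.e. same concept domain but different value domain),
routine-vs-trial documentation (four `MATCHING` concepts), and
cross-institution comparison (eight shared concepts at mixed levels).

What the generator does *not* emulate: natural-language item names,
realistic form sizes and annotation error modes (synonymous CUIs chosen
by different annotators, partial annotation). Passing the ground-truth
tests therefore demonstrates that the cascade is implemented exactly as
specified, not that two independently annotated real registries will be
matched completely — with inconsistent manual annotation, concept domains
differ and items legitimately classify `DIFFERENT`.

## Testing strategy and problem sizes

The classifier is verified against an independent brute-force
re-derivation of the gates (shared no code) on 1000 randomized pairs, and
the end-to-end pipeline against planted ground truth on 200 randomized
layouts of 2–4 forms — sizes chosen so the full suite runs comfortably on
a laptop while every gate and level is exercised thousands of times.
Structural invariants (symmetry, level nesting, totality of the
classification, transitivity of concept equality across `SIMILAR`+ pairs,
matrix/pair consistency, CSV and XML round-trips) are property-tested
under fixed seeds.

## SUS scoring

The usability module scores 10-item System Usability Scale responses:
odd items contribute `rating − 1`, even items `5 − rating`, and the sum
is multiplied by 2.5, giving 0–100 in steps of 2.5. The reported mean is
rounded half-up to one decimal (the convention under which the bundled
12-participant evaluation yields 74.2); the raw mean is exposed
alongside. Ratings outside 1..5 are rejected rather than clamped.

## Known limitations

* Measurement units are parsed tolerantly but ignored — two `IDENTICAL`
  items may still store values in different units.
* Comparison is code-equality based by design: no UMLS graph distance, no
  lexical similarity of names, no cross-terminology mapping. Synonymous
  concepts annotated with different CUIs classify `DIFFERENT`.
* An item's position within its form does not influence the comparison.
* `xlsx` export is not provided; CSV/TSV/HTML cover the export needs.
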