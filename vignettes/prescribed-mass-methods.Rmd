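---
title: "From prescribing records to ingredient mass: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From prescribing records to ingredient mass: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxmass)
```

## The problem

Practice-level prescribing extracts are organised around *presentations*:
a 15-character BNF code identifies a drug, formulation, strength and product
combination, and each monthly row records how many items and what quantity
of that presentation one GP practice dispensed. Nothing in the row says
which chemical substances were dispensed, or how many grams of them.
`rxmass` closes that gap: it resolves every BNF code to its active
pharmaceutical ingredients (APIs) with strengths and medicinal forms, turns
dispensed quantities into kilograms of each ingredient, and aggregates the
result by practice, postcode, month, region and form.

## The resolution model

The UK drug dictionary organises products on four identifier levels:
virtual products (VMP — "amoxicillin 500 mg capsules"), actual products
(AMP — a specific brand/supplier), and their pack-level counterparts (VMPP,
AMPP). Ingredient strengths hang off the VMP as ingredient-strength rows:
numerator value and unit, plus an optional denominator for concentrations
(e.g. 250 mg per 5 ml).

A BNF/SNOMED mapping table links each BNF code to one or more SNOMED codes,
which may sit at any of the four levels. `resolve_snomed()` checks the
product levels before the pack levels — **AMP, then VMP, then VMPP, then
AMPP** — and traverses pack hits up to the VMP that owns the strengths. The
product-before-pack ordering is a design choice: product identifiers are the
direct route to ingredients, while pack matches occur only for a minority of
codes, and checking packs last makes the provenance tag informative about
how direct the resolution was. Codes matching no level are returned tagged
`unresolved` and reported as a fraction; they are never dropped silently.

`build_bnf_catalog()` then emits one *component* per (BNF code, ingredient):
ingredient name, strength, optional denominator, form and provenance. Three
policies matter here:

* **Multi-ingredient products** own one component per ingredient — a
  500 mg/125 mg two-API tablet contributes two masses per record, never a
  blended one.
* **Disagreeing strengths** (a code whose SNOMED codes resolve to different
  strengths for the same ingredient) are kept as flagged *ambiguous*
  variants. Quantification refuses flagged codes to the reject log.
  Averaging was rejected as a design option because it silently corrupts
  mass totals; strength comparison is exact after unit normalisation, with
  no epsilon, since dictionary strengths are exact decimals.
* **Salt qualifiers** in ingredient names ("amoxicillin (as amoxicillin
  trihydrate)") stay in the display name, but the unparenthesised stem is
  the grouping key, so salt forms of one ingredient aggregate together. The
  reported mass is the stated strength mass; no salt-to-base correction is
  attempted, because the dictionary states strengths per presentation and a
  correction would require a curated molecular-weight table — a documented
  limitation.

Presentations whose dispensed quantity has no meaningful ingredient-mass
interpretation are excluded by an ordered, case-insensitive rule set over
form names and product descriptions (devices, appliances, bath additives,
washes, foams, shampoos, sprays, multivitamins;
`default_exclusion_rules()`). Patterns are plain substrings anchored at a
word start — not regular expressions — so the active rule set stays
auditable. Exclusion partitions the catalog; nothing is deleted.

## The mass model

For each record × component pair:

* **Discrete forms** (tablet, capsule — no denominator):
  `mass_kg = quantity × strength × factor_to_kg(unit)`.
* **Concentration forms** (denominator present, e.g. per ml):
  `mass_kg = quantity × strength × factor_to_kg(unit) / denominator_value`,
  with the dispensed quantity interpreted in denominator units (millilitres
  of solution, not bottles). The extract dialect does not state quantity
  units explicitly — they are formulation-dependent — so this interpretation
  is declared rather than inferred, and unit-kind mismatches reject rather
  than guess.
* **Percent strengths** (% w/v, % w/w) are rejected by default: without a
  density assumption they have no defensible mass conversion. The unit
  table is configuration, so a user who accepts a density convention can
  extend it.

Mass uses the dispensed **quantity** only; the item count is carried for
reporting but never multiplied in. Quantity is treated as the total
dispensed for the row, not per-item. Currency fields pass through parsed
but untouched.

The unit table (`default_unit_table()`, or a CSV via `read_unit_table()`)
carries strictly positive factors to kg for mass units and kind tags for
volume/count units; conversions are linear and compose (µg→mg→kg chains
agree with direct factors, tested).

Aggregation (`aggregate_mass()`) is plain summation over key subsets, so
mass is conserved across the roll-up hierarchy: per-API yearly totals equal
the sum of monthly totals, per-practice totals and per-postcode totals (the
suite asserts this at 1e-9 relative tolerance). Outputs keep full floating
precision; rounding is presentation-layer only.

## Geography

Practice postcodes (from the address file, latest period winning when a
practice moves, superseded values logged) are normalised — upper case,
single internal space, a space inserted before the inward code when absent
— and joined to a postcode lookup giving WGS84 lon/lat. Region membership
uses an even-odd ray-casting containment test over every ring of every
polygon, so holes need no winding convention; points exactly on a boundary
edge count as inside (closed polygons — a deterministic tie-break for
practices on a border). Geometry is planar in lon/lat: over health-region
scale polygons the geodesic error is far below the positional error of a
postcode centroid, a documented limitation rather than a hidden one. The
test suite cross-checks containment against an independent winding-number
implementation on 1000 random points.

## The synthetic study and what it shows

`generate_fixture()` writes every input dialect — monthly extracts, the
SNOMED map, six dictionary tables plus form dictionary, the address file,
postcode lookup, boundary GeoJSON and unit table — together with a ledger
of ground-truth contributions, aggregates, reject counts and region
membership. The reference configuration is 20 practices × 12 months × 10
APIs with 4 products per API plus one two-ingredient combination (~10⁴
prescription rows), strengths drawn from
{1, 2, 5, 7.5, 10, 25, 125, 250, 500} mg, one product in three a per-5-ml
oral solution, and 20% of products planted unmapped and 20% in excluded
categories. Planting is round-robin, not Bernoulli, so planted counts are
exact at any size. Quantities are integers from a seeded uniform draw
(6–120 units, ×5 ml for solutions); every derived mass is a deterministic
product of those integers with exact-decimal strengths.

Ledger masses are computed with the same association order as the
quantification path and written with 17 significant digits, so
`verify_ledger()` checks **exact** equality (tolerance 0) of every
contribution and aggregate — summation order is controlled, making
floating-point totals bit-reproducible. Unit tests read those numerics back
with base R's correctly rounded parser for the same reason.

What passing proves: the resolver, mass arithmetic, exclusion and reject
accounting, aggregation and geolocation are exactly self-consistent on
inputs of known truth. What it does not prove: realism. The generator makes
no attempt at realistic prescribing distributions, seasonal shapes,
postcode geography or dictionary quirks (typos, retired codes, VTM-level
records, percent strengths in the wild). Real extracts will exercise the
reject paths far more heavily; the accounting identities
(accepted + rejected = input, kept + excluded = catalog) are the properties
designed to keep that honest.

## Numerical and degenerate-input choices

* BNF codes shorter or longer than 15 characters after trimming are
  rejected with a reason; no padding heuristics.
* Readers stream row-wise semantics: every input row lands in exactly one
  of accepted/rejected, and counts are checked per file.
* Empty inputs are values, not errors (empty mapping → empty catalog;
  header-only extract → zero records with a warning); only structurally
  unusable inputs (missing columns, missing dictionary tables, empty file
  sets) raise hard errors naming the missing piece.
* Catalog construction and aggregation are order-independent (tested by
  shuffling inputs); ties in exclusion are broken by rule order, which is
  part of the configuration.
* Monthly report tables always span the full 12 months, zero-filled, so
  seasonal shapes remain comparable across APIs and years; APIs requested
  but absent appear with 0 kg rather than vanishing.

## Problem sizes

The suite runs its end-to-end checks on the reference 20 × 12 × 10 study
(~10⁴ rows, a few seconds) and smaller 3–4-practice configurations for
property tests; `scripts/acceptance.R` re-runs the reference study from a
seed and reports the pipeline's headline quantities. These sizes were
chosen as the smallest at which every code path (multi-ingredient split,
concentration forms, planted unmapped/excluded products, pack-level
resolution, region membership) is exercised simultaneously.
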