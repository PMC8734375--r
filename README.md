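# rxmass

Estimate the prescribed mass (in kilograms) of every active pharmaceutical
ingredient (API) from practice-level prescribing extracts, resolved to GP
practice, postcode, month, region and medicinal form.

## Who this is for

Monthly prescribing extracts record *presentations* — "Phenergan_Tab 25 mg,
quantity 98" — identified by 15-character BNF codes, not chemical substances.
Researchers in pharmacoepidemiology and environmental science (for example,
predicting pharmaceutical loads reaching wastewater from community
prescribing) need the same data expressed as **kilograms of active ingredient
per place and month**. `rxmass` performs that translation offline and
reproducibly.

## The method

Two steps, mirroring how the UK drug dictionary (dm+d) is organised:

1. **Mapping.** Each BNF code's SNOMED product/pack codes are resolved
   through the product hierarchy — Actual Medicinal Product (AMP) first,
   then Virtual Medicinal Product (VMP), then the pack levels (VMPP, AMPP),
   with pack hits traversed up to their VMP. The VMP's ingredient-strength
   records give, for each code, one *component* per API: ingredient name,
   strength with unit, optional concentration denominator, and medicinal
   form. Multi-ingredient products (e.g. a 500 mg/125 mg co-amoxiclav-style
   tablet) yield one component per ingredient. Presentations with no mass
   interpretation — devices, appliances, bath additives, washes, foams,
   shampoos, sprays, multivitamins — are excluded by a configurable rule
   set.

2. **Quantification.** For each prescription record and component,

   ```
   mass_kg = quantity × strength → kg            (discrete forms)
   mass_kg = quantity × strength → kg / denom    (concentrations, quantity in
                                                  denominator units, e.g. ml)
   ```

   using a unit table of multiplication factors to kg (mg → 1e-6, µg → 1e-9,
   …). Masses are then summed over any subset of
   `{api, practice, postcode, region, period, year, form}`; postcodes come
   from the practice address file joined to a postcode lookup, and region
   membership from even-odd point-in-polygon tests against boundary
   polygons. Records that cannot be quantified honestly — unmapped codes,
   ambiguous strengths, percent strengths — go to a reject log, never into
   the totals.

A deterministic fixture generator (`generate_fixture()`) emulates every
input dialect with a ground-truth ledger, so the entire pipeline can be
verified end to end with exact arithmetic, offline.

## Worked example

Parsing a printed product description and computing one record's mass:

```r
parse_product_description("Phenergan_Tab 25 mg")
#>                  text      stem form_token strength_value strength_unit
#> 1 Phenergan_Tab 25 mg Phenergan        Tab             25            mg

rec  <- tibble::tibble(sha = "Q44", pct = "RTV", practice = "Y04937",
                       bnf_code = "0304010W0BBABAL",
                       bnf_name = "Phenergan_Tab 25 mg", items = 3L,
                       nic = 8.15, act_cost = 7.89, quantity = 98,
                       period = "201801")
comp <- tibble::tibble(bnf_code = "0304010W0BBABAL",
                       api_name = "Promethazine hydrochloride",
                       api = "Promethazine hydrochloride",
                       strength_value = 25, strength_unit = "mg",
                       denominator_value = NA_real_,
                       denominator_unit = NA_character_,
                       form = "tablet", provenance = "AMP",
                       description = "Phenergan_Tab 25 mg",
                       ambiguous = FALSE)
record_mass(rec, comp)$mass_kg
#> [1] 0.00245        # 98 tablets × 25 mg = 2.45 g
```

A full synthetic study — 20 practices × 12 months × 10 APIs — end to end:

```r
d <- tempfile()
generate_fixture(fixture_config(seed = 1), d)
res <- run_pipeline(d)
aggregate_mass(res$contributions, "api")
#> # A tibble: 10 × 2
#>    api         mass_kg
#>  1 Alphacillin  7.51
#>  2 Betaprofen   2.57
#>  3 Deltastatin  3.91
#>  4 Epsilomycin  8.20
#>  ...
verify_ledger(d, res)   # zero rows: pipeline equals ground truth exactly
```

Each `mass_kg` is the year's prescribed kilograms of that ingredient across
the region; records planted as unmapped or excluded appear in
`res$rejects` (3840 of 9840 records under the default planting fractions),
never silently dropped.

Reports mirror the standard analysis views: `targeted_report()` (annual,
monthly, per-practice, per-postcode and per-form tables for a list of
target APIs) and `nontargeted_report()` (postcode-level breakdown and form
shares for one API), with `plot_annual_totals()`, `plot_monthly_trend()`,
`plot_form_shares()` and `export()` for CSV/PNG/EPS/PDF output. A thin
command-line front end lives at `inst/cli/rxmass.R`
(`synth`, `combine`, `build-mapping`, `gp-list`, `quantify`, `report`).

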