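#' Run the full quantification pipeline over a bundle directory
#'
#' Convenience wiring for a directory laid out as [generate_fixture()]
#' writes it (`pdpi/` monthly extracts, `snomed_map.csv`, `dmd/` tables,
#' `addr.csv`, `postcodes.csv`, `regions.geojson`, `units.csv`): combines
#' the monthly files, builds and filters the BNF catalog, geolocates
#' practices and assigns regions, computes mass contributions, and collects
#' the run's row and reject accounting.
#'
#' @param dir Bundle directory.
#' @param rules Exclusion rules, see [default_exclusion_rules()].
#' @return List with `contributions`, `rejects` (quantification rejects),
#'   `reader_rejects`, `catalog`, `excluded`, `unresolved`, `match_rate`,
#'   `geo`, `region_practices` (membership of the first region) and
#'   `file_counts`.
#' @export
run_pipeline <- function(dir, rules = default_exclusion_rules()) {
  combined <- combine_monthly(file.path(dir, "pdpi"))
  snomed <- read_snomed_map(file.path(dir, "snomed_map.csv"))
  dmd <- read_dmd(file.path(dir, "dmd"))
  if (nrow(dmd$violations) > 0) {
    warning("product graph has ", nrow(dmd$violations),
            " integrity violation(s)", call. = FALSE)
  }
  cat_build <- build_bnf_catalog(snomed$map, dmd$graph)
  parts <- apply_exclusions(cat_build$catalog, rules)
  units <- read_unit_table(file.path(dir, "units.csv"))$units

  practices <- read_practices(file.path(dir, "addr.csv"))$practices
  lookup <- read_postcode_lookup(file.path(dir, "postcodes.csv"))
  geo <- geolocate_practices(practices, lookup)
  boundaries <- read_region_boundaries(file.path(dir, "regions.geojson"))
  geo <- assign_regions(geo, boundaries)

  q <- quantify(combined$records, parts$kept, units, geo = geo)
  list(
    contributions = q$contributions,
    rejects = q$rejects,
    reader_rejects = combined$rejects,
    catalog = parts$kept,
    excluded = parts$excluded,
    unresolved = cat_build$unresolved,
    match_rate = cat_build$match_rate,
    geo = geo,
    region_practices = practices_in_region(geo, boundaries[[1]]),
    file_counts = combined$file_counts
  )
}
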