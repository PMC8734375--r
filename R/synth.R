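#' Configuration for the synthetic fixture generator
#'
#' Defines the shape of a generated study: practices, months, APIs, products
#' per API, and the fractions of products deliberately planted as unmapped
#' (present in prescriptions but absent from the SNOMED map) or as
#' excluded-category presentations (bath additives, sprays, shampoos).
#' Fractions are realised exactly by deterministic round-robin assignment,
#' never by sampling, so expected counts hold at any size.
#'
#' @param seed Integer seed; the same seed yields a byte-identical bundle.
#' @param n_practices Number of GP practices.
#' @param n_months Number of monthly extracts (1..48).
#' @param n_apis Number of active ingredients (>= 1; with >= 2 a
#'   two-ingredient combination product is included).
#' @param products_per_api Single-ingredient products per API.
#' @param unmapped_fraction Fraction of products with no SNOMED mapping rows.
#' @param excluded_fraction Fraction of products in excluded presentation
#'   categories.
#' @param start_period First month, `YYYYMM`.
#' @param region Named list `name`, `xmin`, `ymin`, `xmax`, `ymax`: the
#'   rectangular region every practice lies in.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_practices = 20L, n_months = 12L,
                           n_apis = 10L, products_per_api = 4L,
                           unmapped_fraction = 0.2, excluded_fraction = 0.2,
                           start_period = "201801",
                           region = list(name = "Avonshire", xmin = -2.6,
                                         ymin = 51.3, xmax = -2.2, ymax = 51.5)) {
  stopifnot(
    n_apis >= 1, n_practices >= 1, products_per_api >= 1,
    n_months >= 1, n_months <= 48,
    unmapped_fraction >= 0, unmapped_fraction <= 1,
    excluded_fraction >= 0, excluded_fraction <= 1,
    is_valid_period(start_period)
  )
  structure(list(
    seed = as.integer(seed), n_practices = as.integer(n_practices),
    n_months = as.integer(n_months), n_apis = as.integer(n_apis),
    products_per_api = as.integer(products_per_api),
    unmapped_fraction = unmapped_fraction,
    excluded_fraction = excluded_fraction,
    start_period = start_period, region = region
  ), class = "fixture_config")
}

# month sequence YYYYMM starting at start_period
period_seq <- function(start_period, n) {
  y <- as.integer(substr(start_period, 1, 4))
  m <- as.integer(substr(start_period, 5, 6))
  idx <- (m - 1L) + seq_len(n) - 1L
  sprintf("%04d%02d", y + idx %/% 12L, idx %% 12L + 1L)
}

fixture_api_names <- function(n) {
  pool <- c("Alphacillin", "Betaprofen", "Gammazepam", "Deltastatin",
            "Epsilomycin", "Zetaridone", "Etaprazole", "Thetaxetine",
            "Iotafenac", "Kappavir", "Lambdapril", "Mupirocet",
            "Nuvastine", "Xiprolol", "Omicrazole", "Pivastatin")
  if (n > length(pool)) {
    pool <- c(pool, sprintf("Synthadrug%02d", seq_len(n - length(pool))))
  }
  pool[seq_len(n)]
}

# round-robin index planting: k indices spread evenly over 1..n
plant_indices <- function(n, fraction, avoid = integer(0)) {
  k <- round(fraction * n)
  if (k == 0) return(integer(0))
  candidates <- setdiff(seq_len(n), avoid)
  stride <- max(1L, length(candidates) %/% k)
  candidates[((seq_len(k) - 1L) * stride) %% length(candidates) + 1L]
}

# exact-decimal strength pool (mg); keeps fixture masses reproducible
fixture_strengths <- c(1, 2, 5, 7.5, 10, 25, 125, 250, 500)

build_product_plan <- function(config) {
  apis <- fixture_api_names(config$n_apis)
  n_single <- config$n_apis * config$products_per_api
  plan <- tidyr::expand_grid(api_idx = seq_len(config$n_apis),
                             prod_idx = seq_len(config$products_per_api))
  plan$product <- seq_len(nrow(plan))
  plan$api <- apis[plan$api_idx]
  plan$strength <- fixture_strengths[
    (plan$api_idx + 3L * plan$prod_idx) %% length(fixture_strengths) + 1L]
  plan$form <- c("tablet", "capsule", "oral solution")[
    (plan$prod_idx - 1L) %% 3L + 1L]
  plan$is_combo <- FALSE
  if (config$n_apis >= 2) {
    combo <- tibble::tibble(
      api_idx = NA_integer_, prod_idx = NA_integer_,
      product = n_single + 1L, api = NA_character_,
      strength = NA_real_, form = "tablet", is_combo = TRUE
    )
    plan <- dplyr::bind_rows(plan, combo)
  }
  n_products <- nrow(plan)
  idx_unmapped <- plant_indices(n_products, config$unmapped_fraction)
  idx_excluded <- plant_indices(n_products, config$excluded_fraction,
                                avoid = idx_unmapped)
  plan$mapped <- !plan$product %in% idx_unmapped
  plan$excluded <- plan$product %in% idx_excluded
  excl_forms <- c("bath additive", "cutaneous spray", "shampoo")
  plan$form[plan$excluded] <-
    excl_forms[(seq_len(sum(plan$excluded)) - 1L) %% 3L + 1L]
  # concentration products: strength per 5 ml, quantity dispensed in ml
  plan$denominator_value <- ifelse(plan$form == "oral solution", 5, NA_real_)
  plan$denominator_unit <- ifelse(plan$form == "oral solution", "ml", NA_character_)
  plan$bnf_code <- sprintf("%015d", 40000000L + plan$product)
  plan$vmp_id <- as.character(100000L + plan$product * 10L)
  plan
}

# component table: one row per (product, ingredient) sorted as the catalog
# sorts them, so ledger contribution order matches pipeline output order
plan_components <- function(plan, apis) {
  single <- plan[!plan$is_combo, ]
  comp <- tibble::tibble(
    product = single$product, api = single$api,
    api_name = ifelse(single$prod_idx %% 2L == 0L,
                      paste0(single$api, " (as ", tolower(single$api),
                             " trihydrate)"),
                      single$api),
    strength = single$strength
  )
  combo <- plan[plan$is_combo, ]
  if (nrow(combo) == 1) {
    comp <- dplyr::bind_rows(comp, tibble::tibble(
      product = combo$product,
      api = apis[1:2],
      api_name = c(paste0(apis[1], " (as ", tolower(apis[1]), " trihydrate)"),
                   paste0(apis[2], " (as potassium ", tolower(apis[2]), ")")),
      strength = c(500, 125)
    ))
  }
  dplyr::arrange(comp, .data$product, .data$api, .data$strength)
}

form_abbrev <- function(form) {
  c("tablet" = "Tab", "capsule" = "Cap", "oral solution" = "Oral Soln",
    "bath additive" = "Bath Additive", "cutaneous spray" = "Spray",
    "shampoo" = "Sha")[form]
}

#' Generate a complete synthetic input bundle with a ground-truth ledger
#'
#' Writes every input dialect the pipeline consumes — monthly prescribing
#' extracts, BNF/SNOMED mapping, the six dm+d hierarchy tables plus form
#' dictionary, practice ADDR file, postcode lookup, region boundary GeoJSON
#' and unit table — together with a ledger of known-true per-contribution
#' masses, aggregate totals, reject counts and region membership. The same
#' seed always yields a byte-identical bundle.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, the `config`, the product `plan`
#'   and the in-memory `ledger` (`contributions`, `aggregates`, `counts`).
#' @export
generate_fixture <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pdpi"), showWarnings = FALSE)
  dir.create(file.path(dir, "dmd"), showWarnings = FALSE)
  dir.create(file.path(dir, "ledger"), showWarnings = FALSE)
  set.seed(config$seed)

  apis <- fixture_api_names(config$n_apis)
  plan <- build_product_plan(config)
  comp <- plan_components(plan, apis)
  periods <- period_seq(config$start_period, config$n_months)

  ## ---- practices, postcodes, geography ----
  practices <- tibble::tibble(
    practice = sprintf("P%05d", seq_len(config$n_practices)),
    name = sprintf("Practice %02d Surgery", seq_len(config$n_practices)),
    address = sprintf("%d High Street, Synthtown", seq_len(config$n_practices)),
    postcode_idx = (seq_len(config$n_practices) - 1L) %/% 2L + 1L
  )
  n_pc <- max(practices$postcode_idx)
  postcodes <- tibble::tibble(
    postcode_idx = seq_len(n_pc),
    postcode = sprintf("BA%d %d%s%s",
                       (seq_len(n_pc) - 1L) %/% 9L + 1L,
                       (seq_len(n_pc) - 1L) %% 9L + 1L,
                       LETTERS[(seq_len(n_pc) * 3L) %% 26L + 1L],
                       LETTERS[(seq_len(n_pc) * 7L) %% 26L + 1L]),
    lon = config$region$xmin + (config$region$xmax - config$region$xmin) *
      seq_len(n_pc) / (n_pc + 1L),
    lat = config$region$ymin + (config$region$ymax - config$region$ymin) *
      seq_len(n_pc) / (n_pc + 1L)
  )
  practices <- dplyr::left_join(practices, postcodes, by = "postcode_idx")

  ## ---- dm+d tables ----
  ingredients <- dplyr::distinct(comp, .data$api_name)
  ingredients <- tibble::tibble(
    ingredient_id = as.character(9000L + seq_len(nrow(ingredients))),
    name = ingredients$api_name
  )
  forms <- tibble::tibble(
    form_id = sprintf("F%02d", seq_along(unique(plan$form))),
    name = unique(plan$form)
  )
  vmp_name <- function(p) {
    cn <- comp[comp$product == p, ]
    row <- plan[plan$product == p, ]
    paste0(paste(cn$api, collapse = "/"), " ",
           paste(cn$strength, collapse = "mg/"), "mg ", row$form)
  }
  vmps <- tibble::tibble(
    vmp_id = plan$vmp_id,
    name = vapply(plan$product, vmp_name, character(1)),
    form_id = forms$form_id[match(plan$form, forms$name)]
  )
  vpi <- dplyr::left_join(comp, plan[, c("product", "vmp_id",
                                         "denominator_value",
                                         "denominator_unit")],
                          by = "product")
  vpi <- tibble::tibble(
    vmp_id = vpi$vmp_id,
    ingredient_id = ingredients$ingredient_id[match(vpi$api_name,
                                                    ingredients$name)],
    strength_numerator_value = vpi$strength,
    strength_numerator_unit = "mg",
    strength_denominator_value = vpi$denominator_value,
    strength_denominator_unit = vpi$denominator_unit
  )
  base <- as.integer(plan$vmp_id)
  amps <- tibble::tibble(
    amp_id = as.character(c(base + 1L, base + 2L)),
    vmp_id = c(plan$vmp_id, plan$vmp_id),
    name = c(paste0(vmps$name, " (Genera Labs)"),
             paste0(vmps$name, " (Brandon Pharma)")),
    supplier = rep(c("Genera Labs", "Brandon Pharma"), each = nrow(plan))
  )
  vmpps <- tibble::tibble(
    vmpp_id = as.character(c(base + 3L, base + 4L)),
    vmp_id = c(plan$vmp_id, plan$vmp_id),
    pack_size = rep(c(28, 100), each = nrow(plan)),
    pack_unit = rep(ifelse(plan$form == "oral solution", "ml", "tablet"), 2)
  )
  ampps <- tibble::tibble(
    ampp_id = as.character(c(base + 5L, base + 6L)),
    amp_id = as.character(c(base + 1L, base + 2L)),
    vmpp_id = as.character(c(base + 3L, base + 4L))
  )

  ## ---- SNOMED mapping: 1 AMP + 1 VMPP + 2 AMPP codes per mapped product ----
  mapped <- plan[plan$mapped, ]
  mb <- as.integer(mapped$vmp_id)
  descr <- function(p) {
    cn <- comp[comp$product == p, ]
    row <- plan[plan$product == p, ]
    paste0(paste(cn$api, collapse = "/"), "_", form_abbrev(row$form), " ",
           paste(cn$strength, collapse = " mg/"), " mg")
  }
  mapped_desc <- vapply(mapped$product, descr, character(1))
  snomed_map <- tibble::tibble(
    bnf_code = rep(mapped$bnf_code, 4L),
    snomed_code = as.character(c(mb + 1L, mb + 3L, mb + 5L, mb + 6L)),
    description = rep(mapped_desc, 4L)
  )
  snomed_map <- dplyr::arrange(snomed_map, .data$bnf_code, .data$snomed_code)

  ## ---- prescriptions: every practice x product x month ----
  month_grid <- tidyr::expand_grid(practice = practices$practice,
                                   product = plan$product)
  n_rows_month <- nrow(month_grid)
  all_desc <- vapply(plan$product, descr, character(1))
  pdpi <- lapply(periods, function(per) {
    qty <- sample(6:120, n_rows_month, replace = TRUE)
    is_soln <- plan$form[month_grid$product] == "oral solution"
    qty[is_soln] <- qty[is_soln] * 5L   # dispensed millilitres
    items <- pmax(1L, qty %/% 28L)
    tibble::tibble(
      sha = "Q99", pct = "11X",
      practice = month_grid$practice,
      bnf_code = plan$bnf_code[month_grid$product],
      bnf_name = all_desc[month_grid$product],
      items = items,
      nic = round(items * 2.15, 2),
      act_cost = round(items * 1.98, 2),
      quantity = as.numeric(qty),
      period = per
    )
  })
  names(pdpi) <- periods
  for (per in periods) {
    write_prescriptions(pdpi[[per]],
                        file.path(dir, "pdpi", paste0("PDPI_", per, ".csv")))
  }

  ## ---- remaining input files ----
  readr::write_csv(snomed_map, file.path(dir, "snomed_map.csv"),
                   progress = FALSE)
  dmd <- list(ingredient = ingredients, vmp = vmps, vpi = vpi, amp = amps,
              vmpp = vmpps, ampp = ampps, form = forms)
  for (nm in names(dmd)) {
    readr::write_csv(dmd[[nm]], file.path(dir, "dmd", paste0(nm, ".csv")),
                     progress = FALSE)
  }
  addr <- tibble::tibble(
    period = config$start_period,
    practice = practices$practice, name = practices$name,
    address = practices$address, postcode = practices$postcode
  )
  names(addr) <- c("PERIOD", "PRACTICE", "NAME", "ADDRESS", "POSTCODE")
  readr::write_csv(addr, file.path(dir, "addr.csv"), progress = FALSE)
  nspl <- tibble::tibble(pcds = postcodes$postcode, long = postcodes$lon,
                         lat = postcodes$lat)
  readr::write_csv(nspl, file.path(dir, "postcodes.csv"), progress = FALSE)
  write_boundary_geojson(config$region, file.path(dir, "regions.geojson"))
  readr::write_csv(default_unit_table(), file.path(dir, "units.csv"),
                   progress = FALSE)

  ## ---- ground-truth ledger ----
  # kept components (mapped, not excluded), in pipeline emission order:
  # record order (period file, then practice x product) x components sorted
  # by (api, strength) within a product
  kept <- plan$mapped & !plan$excluded
  comp_full <- dplyr::left_join(
    comp, plan[, c("product", "bnf_code", "form", "denominator_value")],
    by = "product"
  )
  ledger_contrib <- dplyr::bind_rows(lapply(periods, function(per) {
    recs <- dplyr::mutate(pdpi[[per]], product = month_grid$product)
    recs <- recs[kept[recs$product], ]
    # expand record x component keeping record order then component order
    joined <- dplyr::inner_join(recs, comp_full, by = c("product", "bnf_code"),
                                relationship = "many-to-many")
    denom <- dplyr::coalesce(joined$denominator_value, 1)
    tibble::tibble(
      practice = joined$practice,
      api = joined$api,
      period = joined$period,
      form = joined$form,
      bnf_code = joined$bnf_code,
      quantity = joined$quantity,
      # strength converted to kg first, then scaled by quantity: the same
      # association the quantification path uses, so equality is exact
      mass_kg = joined$quantity * (joined$strength * 1e-6) / denom
    )
  }))
  ledger_contrib <- dplyr::left_join(
    ledger_contrib,
    dplyr::select(practices, "practice", "postcode"),
    by = "practice"
  )
  agg <- function(keys) {
    ledger_contrib |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(mass_kg = sum(.data$mass_kg), .groups = "drop") |>
      dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  }
  aggregates <- list(
    api = agg("api"),
    api_period = agg(c("api", "period")),
    api_practice = agg(c("api", "practice")),
    api_postcode = agg(c("api", "postcode"))
  )
  counts <- list(
    n_products = nrow(plan),
    n_unmapped_codes = sum(!plan$mapped),
    n_excluded_products = sum(plan$excluded),
    rows_per_file = n_rows_month,
    n_files = length(periods),
    expected_quantify_rejects =
      length(periods) * config$n_practices * sum(!kept),
    region_practices = sort(practices$practice)
  )
  write_ledger_csv(ledger_contrib, file.path(dir, "ledger", "contributions.csv"))
  for (nm in names(aggregates)) {
    write_ledger_csv(aggregates[[nm]],
                     file.path(dir, "ledger", paste0("total_", nm, ".csv")))
  }
  jsonlite::write_json(counts, file.path(dir, "ledger", "counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = dir, config = config, plan = plan,
                 ledger = list(contributions = ledger_contrib,
                               aggregates = aggregates, counts = counts)))
}

# ledger masses are written with 17 significant digits so the stored decimal
# parses back to the identical double and exact-equality checks stay exact
write_ledger_csv <- function(df, path) {
  for (cl in names(df)) {
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  readr::write_csv(df, path, progress = FALSE)
}

# read ledger numerics as text and convert with base strtod: correctly
# rounded, so the 17-digit decimals recover the exact stored doubles
read_ledger_csv <- function(path, num_cols) {
  df <- read_csv_chr(path)
  for (cl in intersect(num_cols, names(df))) df[[cl]] <- as.numeric(df[[cl]])
  df
}

# one-rectangle GeoJSON FeatureCollection
write_boundary_geojson <- function(region, path) {
  ring <- list(
    c(region$xmin, region$ymin), c(region$xmax, region$ymin),
    c(region$xmax, region$ymax), c(region$xmin, region$ymax),
    c(region$xmin, region$ymin)
  )
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(name = region$name),
      geometry = list(type = "Polygon", coordinates = list(ring))
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Check pipeline outputs against a bundle's ground-truth ledger
#'
#' Compares per-contribution masses, the four ledger aggregate levels,
#' quantification reject counts and region membership against the ledger
#' written by [generate_fixture()]. Mismatches are returned as data; an
#' untouched pipeline yields a zero-row report.
#'
#' @param dir Bundle directory.
#' @param results Pipeline results, minimally `list(contributions = ...)`;
#'   `rejects` and `region_practices` are checked when present (as produced
#'   by [run_pipeline()]).
#' @param tolerance Absolute tolerance on masses (default 0: exact).
#' @return Tibble `(component, key, expected, actual)`; zero rows iff
#'   everything matches.
#' @export
verify_ledger <- function(dir, results, tolerance = 0) {
  mism <- list()
  push <- function(component, key, expected, actual) {
    mism[[length(mism) + 1L]] <<- tibble::tibble(
      component = component, key = key,
      expected = as.character(expected), actual = as.character(actual)
    )
  }
  led <- read_ledger_csv(file.path(dir, "ledger", "contributions.csv"),
                         c("quantity", "mass_kg"))
  keys <- c("practice", "period", "bnf_code", "api")
  got <- dplyr::rename(results$contributions, bnf_code = "source_bnf_code")
  cmp <- dplyr::full_join(
    dplyr::summarise(dplyr::group_by(led, dplyr::across(dplyr::all_of(keys))),
                     expected = sum(.data$mass_kg), .groups = "drop"),
    dplyr::summarise(dplyr::group_by(got, dplyr::across(dplyr::all_of(keys))),
                     actual = sum(.data$mass_kg), .groups = "drop"),
    by = keys
  )
  bad <- is.na(cmp$expected) | is.na(cmp$actual) |
    abs(cmp$expected - cmp$actual) > tolerance
  for (i in which(bad)) {
    push("contribution", paste(cmp[i, keys], collapse = "|"),
         cmp$expected[i], cmp$actual[i])
  }
  for (nm in c("api", "api_period", "api_practice", "api_postcode")) {
    lk <- strsplit(nm, "_")[[1]]
    lk[lk == "api"] <- "api"
    keyset <- unique(c("api", setdiff(lk, "api")))
    led_agg <- read_ledger_csv(file.path(dir, "ledger",
                                         paste0("total_", nm, ".csv")),
                               "mass_kg")
    got_agg <- aggregate_mass(results$contributions, keyset)
    cmp <- dplyr::full_join(
      dplyr::rename(led_agg, expected = "mass_kg"),
      dplyr::rename(got_agg, actual = "mass_kg"),
      by = keyset
    )
    bad <- is.na(cmp$expected) | is.na(cmp$actual) |
      abs(cmp$expected - cmp$actual) > tolerance
    for (i in which(bad)) {
      push(paste0("aggregate:", nm),
           paste(unlist(cmp[i, keyset]), collapse = "|"),
           cmp$expected[i], cmp$actual[i])
    }
  }
  counts <- jsonlite::read_json(file.path(dir, "ledger", "counts.json"),
                                simplifyVector = TRUE)
  if (!is.null(results$rejects)) {
    if (nrow(results$rejects) != counts$expected_quantify_rejects) {
      push("reject_count", "quantify", counts$expected_quantify_rejects,
           nrow(results$rejects))
    }
  }
  if (!is.null(results$region_practices)) {
    exp_m <- counts$region_practices
    got_m <- results$region_practices
    if (!identical(sort(exp_m), sort(got_m))) {
      push("region_membership", "practices",
           paste(setdiff(exp_m, got_m), collapse = ","),
           paste(setdiff(got_m, exp_m), collapse = ","))
    }
  }
  if (length(mism) == 0) {
    return(tibble::tibble(component = character(), key = character(),
                          expected = character(), actual = character()))
  }
  dplyr::bind_rows(mism)
}
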