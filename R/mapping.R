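#' Resolve a SNOMED product or pack code through the hierarchy
#'
#' A SNOMED code from the BNF mapping file may identify a product (AMP or
#' VMP) or a product pack (VMPP or AMPP). Resolution tries the product
#' levels before the pack levels — AMP, then VMP, then VMPP, then AMPP —
#' and traverses pack hits up to their VMP, the level that owns ingredient
#' strengths. Codes absent from all four identifier spaces come back tagged
#' `unresolved`, never dropped.
#'
#' @param code A single SNOMED code (character or numeric).
#' @param graph A validated [product_graph()].
#' @return List with `code`, `level` (`"AMP"`, `"VMP"`, `"VMPP"`, `"AMPP"` or
#'   `"unresolved"`), `vmp_id` (`NA` when unresolved), `amp_id` (when the hit
#'   went through an AMP or AMPP) and `pack` (pack size/unit for pack-level
#'   hits).
#' @export
resolve_snomed <- function(code, graph) {
  stopifnot(length(code) == 1)
  r <- resolve_snomed_all(as.character(code), graph)
  pack <- if (!is.na(r$pack_size[1])) {
    list(size = r$pack_size[1], unit = r$pack_unit[1])
  }
  list(code = r$snomed_code[1], level = r$level[1], vmp_id = r$vmp_id[1],
       amp_id = r$amp_id[1], pack = pack)
}

# vectorised resolver: one row per input code, precedence AMP > VMP > VMPP > AMPP
resolve_snomed_all <- function(codes, graph) {
  codes <- as.character(codes)
  i_amp <- match(codes, graph$amps$amp_id)
  i_vmp <- match(codes, graph$vmps$vmp_id)
  i_vmpp <- match(codes, graph$vmpps$vmpp_id)
  i_ampp <- match(codes, graph$ampps$ampp_id)
  level <- dplyr::case_when(
    !is.na(i_amp) ~ "AMP",
    !is.na(i_vmp) ~ "VMP",
    !is.na(i_vmpp) ~ "VMPP",
    !is.na(i_ampp) ~ "AMPP",
    TRUE ~ "unresolved"
  )
  # AMPP traverses via its AMP; VMPP directly carries its VMP
  ampp_amp <- graph$ampps$amp_id[i_ampp]
  amp_id <- dplyr::case_when(
    level == "AMP" ~ codes,
    level == "AMPP" ~ ampp_amp,
    TRUE ~ NA_character_
  )
  vmp_id <- dplyr::case_when(
    level == "AMP" ~ graph$amps$vmp_id[i_amp],
    level == "VMP" ~ codes,
    level == "VMPP" ~ graph$vmpps$vmp_id[i_vmpp],
    level == "AMPP" ~ graph$amps$vmp_id[match(ampp_amp, graph$amps$amp_id)],
    TRUE ~ NA_character_
  )
  i_pack <- dplyr::if_else(level == "AMPP",
                           match(graph$ampps$vmpp_id[i_ampp], graph$vmpps$vmpp_id),
                           i_vmpp)
  has_pack <- level %in% c("VMPP", "AMPP")
  tibble::tibble(
    snomed_code = codes,
    level = level,
    vmp_id = vmp_id,
    amp_id = amp_id,
    pack_size = ifelse(has_pack, graph$vmpps$pack_size[i_pack], NA),
    pack_unit = ifelse(has_pack, graph$vmpps$pack_unit[i_pack], NA_character_)
  )
}

#' Build the BNF-to-ingredient catalog
#'
#' The first mapping step: every `(bnf_code, snomed_code)` pair is resolved
#' through the product hierarchy to a VMP, whose ingredient-strength rows
#' yield one catalog component per active ingredient — so a two-ingredient
#' product (e.g. an amoxicillin 500 mg / clavulanic acid 125 mg tablet) owns
#' two components under its one BNF code. Components identical across a
#' code's many SNOMED codes are deduplicated, keeping the
#' highest-precedence provenance. When a code's SNOMED codes disagree on
#' strength for the same ingredient, all variants are kept and flagged
#' `ambiguous`; downstream quantification refuses flagged codes rather than
#' averaging them. Unresolved pairs are reported, never dropped.
#'
#' @param map Tibble of mapping rows (`bnf_code`, `snomed_code`,
#'   `description`), as from [read_snomed_map()].
#' @param graph A [product_graph()].
#' @return List with:
#'   * `catalog`: tibble `(bnf_code, api_name, api, strength_value,
#'     strength_unit, denominator_value, denominator_unit, form, provenance,
#'     description, ambiguous)`; `api` is the unparenthesised ingredient-name
#'     stem used as the grouping key.
#'   * `unresolved`: mapping rows whose SNOMED code hit no hierarchy level.
#'   * `match_rate`: fraction of distinct BNF codes that gained at least one
#'     component.
#' @export
build_bnf_catalog <- function(map, graph) {
  empty <- tibble::tibble(
    bnf_code = character(), api_name = character(), api = character(),
    strength_value = numeric(), strength_unit = character(),
    denominator_value = numeric(), denominator_unit = character(),
    form = character(), provenance = character(), description = character(),
    ambiguous = logical()
  )
  if (nrow(map) == 0) {
    return(list(catalog = empty, unresolved = map, match_rate = NA_real_))
  }
  res <- resolve_snomed_all(map$snomed_code, graph)
  rows <- dplyr::bind_cols(map[, c("bnf_code", "description")], res)
  unresolved <- rows[rows$level == "unresolved",
                     c("bnf_code", "snomed_code", "description")]
  hits <- rows[rows$level != "unresolved", , drop = FALSE]
  if (nrow(hits) == 0) {
    return(list(catalog = empty, unresolved = unresolved, match_rate = 0))
  }

  vmps <- dplyr::left_join(
    graph$vmps,
    dplyr::rename(graph$forms, form = "name"),
    by = "form_id"
  )
  components <- hits |>
    dplyr::inner_join(graph$vpi, by = "vmp_id", relationship = "many-to-many") |>
    dplyr::left_join(
      dplyr::select(graph$ingredients, "ingredient_id", api_name = "name"),
      by = "ingredient_id"
    ) |>
    dplyr::left_join(dplyr::select(vmps, "vmp_id", "form"), by = "vmp_id") |>
    dplyr::mutate(
      api = api_stem(.data$api_name),
      provenance = factor(.data$level, levels = c("AMP", "VMP", "VMPP", "AMPP"))
    ) |>
    dplyr::select(
      "bnf_code", "api_name", "api",
      strength_value = "strength_numerator_value",
      strength_unit = "strength_numerator_unit",
      denominator_value = "strength_denominator_value",
      denominator_unit = "strength_denominator_unit",
      "form", "provenance", "description"
    )

  catalog <- components |>
    dplyr::arrange(.data$bnf_code, .data$api, .data$provenance) |>
    dplyr::distinct(.data$bnf_code, .data$api, .data$api_name,
                    .data$strength_value, .data$strength_unit,
                    .data$denominator_value, .data$denominator_unit,
                    .data$form, .keep_all = TRUE) |>
    dplyr::group_by(.data$bnf_code, .data$api) |>
    dplyr::mutate(ambiguous = dplyr::n() > 1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(provenance = as.character(.data$provenance)) |>
    dplyr::arrange(.data$bnf_code, .data$api, .data$strength_value)

  n_codes <- dplyr::n_distinct(map$bnf_code)
  list(
    catalog = catalog[, names(empty)],
    unresolved = unresolved,
    match_rate = dplyr::n_distinct(catalog$bnf_code) / n_codes
  )
}

# unit tokens recognised when parsing strengths out of product descriptions
strength_unit_pattern <- "(?:mg|mcg|microgram(?:me)?s?|ng|g|kg|ml|litres?)"

#' Parse a product description string
#'
#' Extracts the product-name stem (before the first underscore), the
#' medicinal-form token that follows it, and a trailing
#' `"<number> <unit>"` strength when one is present (e.g.
#' `"Phenergan_Tab 25 mg"` parses to stem `"Phenergan"`, form token `"Tab"`,
#' strength 25 mg). Used for validation against catalog strengths and as
#' fallback display metadata — a parsed strength never overrides a
#' hierarchy-supplied strength when both exist.
#'
#' @param text Character vector of product descriptions.
#' @return Tibble with `text`, `stem`, `form_token`, `strength_value`,
#'   `strength_unit` (`NA` where no numeric strength is present).
#' @export
#' @examples
#' parse_product_description(c("Phenergan_Tab 25 mg", "Sod Chlor_Irrig Soln"))
parse_product_description <- function(text) {
  has_us <- stringr::str_detect(text, stringr::fixed("_"))
  stem <- dplyr::if_else(has_us, stringr::str_extract(text, "^[^_]*"), text)
  rest <- dplyr::if_else(has_us, stringr::str_remove(text, "^[^_]*_"), "")
  pat <- paste0("([0-9]+(?:\\.[0-9]+)?)\\s*(", strength_unit_pattern, ")\\b")
  m <- stringr::str_match(rest, stringr::regex(pat, ignore_case = TRUE))
  form_token <- rest
  hit <- !is.na(m[, 1])
  if (any(hit)) {
    pos <- stringr::str_locate(rest[hit], stringr::fixed(m[hit, 1]))[, 1]
    form_token[hit] <- stringr::str_sub(rest[hit], 1L, pos - 1L)
  }
  form_token <- stringr::str_trim(form_token)
  tibble::tibble(
    text = text,
    stem = stringr::str_trim(stem),
    form_token = dplyr::na_if(form_token, ""),
    strength_value = as.numeric(m[, 2]),
    strength_unit = tolower(m[, 3])
  )
}

#' Default exclusion rules
#'
#' The stock rule set removes product categories whose prescribed quantity
#' has no meaningful active-ingredient mass interpretation: medical devices
#' and appliances, bath additives, washes, foams, shampoos, sprays, and
#' multivitamin capsules and tablets. Each rule is a case-insensitive plain
#' substring anchored at a word start (not a regular expression), matched
#' against both the medicinal-form name and the product description, in
#' order; the first matching rule wins.
#'
#' @return Tibble with columns `rule` and `pattern`.
#' @export
default_exclusion_rules <- function() {
  tibble::tribble(
    ~rule,            ~pattern,
    "device",         "device",
    "appliance",      "appliance",
    "bath additive",  "bath additive",
    "wash",           "wash",
    "foam",           "foam",
    "shampoo",        "shampoo",
    "spray",          "spray",
    "multivitamin",   "multivitamin"
  )
}

#' Partition a catalog into kept and excluded entries
#'
#' Every catalog entry lands in exactly one of `kept` or `excluded`;
#' `nrow(kept) + nrow(excluded)` equals the catalog size. Excluded entries
#' carry the name of the first rule that matched their form name or product
#' description.
#'
#' @param catalog Catalog tibble from [build_bnf_catalog()].
#' @param rules Ordered rule tibble, see [default_exclusion_rules()].
#' @return List with `kept` and `excluded` (the latter with a `rule` column).
#' @export
apply_exclusions <- function(catalog, rules = default_exclusion_rules()) {
  matched_rule <- rep(NA_character_, nrow(catalog))
  hay <- paste(dplyr::coalesce(catalog$form, ""),
               dplyr::coalesce(catalog$description, ""))
  for (i in seq_len(nrow(rules))) {
    rx <- stringr::regex(paste0("\\b", escape_pattern(rules$pattern[i])),
                         ignore_case = TRUE)
    hit <- is.na(matched_rule) & stringr::str_detect(hay, rx)
    matched_rule[hit] <- rules$rule[i]
  }
  keep <- is.na(matched_rule)
  list(
    kept = catalog[keep, , drop = FALSE],
    excluded = dplyr::mutate(catalog[!keep, , drop = FALSE],
                             rule = matched_rule[!keep])
  )
}

# escape regex metacharacters so rule patterns stay plain substrings
escape_pattern <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
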