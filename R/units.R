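#' Built-in unit-of-measure table
#'
#' Units of measure with multiplication factors to kilograms. Mass units carry
#' a strictly positive `factor_to_kg`; volume and count units carry the kind
#' only (they can never be converted to mass without a density assumption and
#' are rejected by [unit_to_kg()]).
#'
#' @return A tibble with columns `unit`, `kind` (`"mass"`, `"volume"` or
#'   `"count"`) and `factor_to_kg` (`NA` for non-mass units).
#' @export
#' @examples
#' default_unit_table()
default_unit_table <- function() {
  tibble::tribble(
    ~unit,        ~kind,    ~factor_to_kg,
    "ng",         "mass",   1e-12,
    "microgram",  "mass",   1e-9,
    "mcg",        "mass",   1e-9,
    "mg",         "mass",   1e-6,
    "g",          "mass",   1e-3,
    "gram",       "mass",   1e-3,
    "kg",         "mass",   1,
    "ml",         "volume", NA_real_,
    "litre",      "volume", NA_real_,
    "unit",       "count",  NA_real_,
    "tablet",     "count",  NA_real_,
    "capsule",    "count",  NA_real_,
    "dose",       "count",  NA_real_
  )
}

#' Read a unit-of-measure table
#'
#' Reads a CSV with columns `unit`, `kind` and `factor_to_kg`. Mass rows must
#' carry a strictly positive factor; rows with an unknown kind or a
#' non-positive factor are rejected, never silently dropped.
#'
#' @param path Path to the CSV file.
#' @return A list with elements `units` (the accepted table, same shape as
#'   [default_unit_table()]) and `rejects` (rejected rows with a `reason`
#'   column).
#' @export
read_unit_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  raw$factor_to_kg <- suppressWarnings(as.numeric(raw$factor_to_kg))
  bad_kind <- !raw$kind %in% c("mass", "volume", "count")
  bad_factor <- raw$kind == "mass" & (is.na(raw$factor_to_kg) | raw$factor_to_kg <= 0)
  reason <- dplyr::case_when(
    bad_kind ~ paste0("unknown unit kind: ", raw$kind),
    bad_factor ~ "mass unit without a strictly positive factor_to_kg",
    TRUE ~ NA_character_
  )
  list(
    units = raw[is.na(reason), , drop = FALSE],
    rejects = dplyr::mutate(raw[!is.na(reason), , drop = FALSE],
                            reason = reason[!is.na(reason)])
  )
}

#' Convert a mass quantity to kilograms
#'
#' Linear conversion via the unit table: `value * factor_to_kg(unit)`.
#'
#' @param value Numeric vector of magnitudes.
#' @param unit Character vector of unit symbols (recycled against `value`).
#' @param units A unit table, see [default_unit_table()].
#' @return Numeric vector of masses in kg.
#' @export
#' @examples
#' unit_to_kg(25, "mg")      # 2.5e-05
#' unit_to_kg(500, "microgram")  # 5e-07
unit_to_kg <- function(value, unit, units = default_unit_table()) {
  stopifnot(is.numeric(value))
  idx <- match(unit, units$unit)
  unknown <- unique(unit[is.na(idx)])
  if (length(unknown) > 0) {
    stop("unknown unit(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  nonmass <- unique(unit[units$kind[idx] != "mass"])
  if (length(nonmass) > 0) {
    stop("not a mass unit: ", paste(nonmass, collapse = ", "), call. = FALSE)
  }
  value * units$factor_to_kg[idx]
}

# TRUE for units present in the table with kind "mass"
is_mass_unit <- function(unit, units = default_unit_table()) {
  idx <- match(unit, units$unit)
  !is.na(idx) & units$kind[idx] == "mass"
}
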