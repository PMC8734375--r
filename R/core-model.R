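#' Normalise a BNF presentation code
#'
#' Strips surrounding whitespace and quote characters (mapping files often
#' quote codes to protect leading zeros). No padding is applied: a BNF
#' presentation code identifies drug, formulation, strength and product in
#' exactly 15 characters, and codes of any other length are treated as
#' malformed by the validators.
#'
#' @param x Character vector of raw codes.
#' @return Character vector of cleaned codes.
#' @export
#' @examples
#' normalise_bnf_code(" '0501050B0AAACAC' ")
normalise_bnf_code <- function(x) {
  stringr::str_remove_all(stringr::str_trim(x), "^['\"]|['\"]$")
}

#' @rdname normalise_bnf_code
#' @export
is_valid_bnf_code <- function(x) {
  !is.na(x) & nchar(normalise_bnf_code(x)) == 15L
}

# period must be YYYYMM with month 01..12
is_valid_period <- function(x) {
  ok <- !is.na(x) & grepl("^[0-9]{6}$", x)
  m <- suppressWarnings(as.integer(substr(x, 5, 6)))
  ok & !is.na(m) & m >= 1L & m <= 12L
}

pdpi_columns <- c("SHA", "PCT", "PRACTICE", "BNF CODE", "BNF NAME",
                  "ITEMS", "NIC", "ACT COST", "QUANTITY", "PERIOD")

pdpi_internal <- c("sha", "pct", "practice", "bnf_code", "bnf_name",
                   "items", "nic", "act_cost", "quantity", "period")

#' Validate raw prescription rows
#'
#' Splits a raw character table (internal column names) into accepted
#' [PrescriptionRecord][read_prescriptions] rows and a reject log. Nothing is
#' silently dropped: `nrow(accepted) + nrow(rejected) == nrow(raw)`.
#'
#' Acceptance requires a 15-character BNF code, a `YYYYMM` period with month
#' in 1..12, a non-negative numeric quantity and a non-negative integer item
#' count. Currency fields are parsed as decimals and carried through; they
#' play no role in mass computation.
#'
#' @param raw Tibble of character columns named as `pdpi` internal fields.
#' @return List with `records` (typed tibble) and `rejects` (original fields
#'   plus `reason`).
#' @keywords internal
validate_prescription_rows <- function(raw) {
  bnf <- normalise_bnf_code(raw$bnf_code)
  items <- suppressWarnings(as.numeric(raw$items))
  quantity <- suppressWarnings(as.numeric(raw$quantity))
  reason <- dplyr::case_when(
    nchar(bnf) != 15L | is.na(bnf) ~ "bnf_code not 15 characters",
    !is_valid_period(raw$period) ~ "period not a valid YYYYMM",
    is.na(quantity) ~ "quantity not numeric",
    quantity < 0 ~ "quantity negative",
    is.na(items) ~ "items not numeric",
    items < 0 ~ "items negative",
    items != floor(items) ~ "items not an integer",
    TRUE ~ NA_character_
  )
  ok <- is.na(reason)
  records <- tibble::tibble(
    sha = raw$sha[ok],
    pct = raw$pct[ok],
    practice = raw$practice[ok],
    bnf_code = bnf[ok],
    bnf_name = raw$bnf_name[ok],
    items = as.integer(items[ok]),
    nic = suppressWarnings(as.numeric(raw$nic[ok])),
    act_cost = suppressWarnings(as.numeric(raw$act_cost[ok])),
    quantity = quantity[ok],
    period = raw$period[ok]
  )
  rejects <- dplyr::mutate(raw[!ok, , drop = FALSE], reason = reason[!ok])
  list(records = records, rejects = rejects)
}

#' Construct a dm+d-style product graph
#'
#' Bundles the six hierarchy tables (plus the optional form dictionary) into
#' a `product_graph` object. Tables are coerced to tibbles with the canonical
#' columns; identifiers are stored as character so that numeric SNOMED codes
#' of any length survive untouched.
#'
#' @param ingredients Tibble `(ingredient_id, name)`.
#' @param vmps Tibble `(vmp_id, name, form_id)`.
#' @param vpi Tibble `(vmp_id, ingredient_id, strength_numerator_value,
#'   strength_numerator_unit, strength_denominator_value,
#'   strength_denominator_unit)`; the denominator pair may be `NA` for
#'   discrete forms.
#' @param amps Tibble `(amp_id, vmp_id, name, supplier)`.
#' @param vmpps Tibble `(vmpp_id, vmp_id, pack_size, pack_unit)`.
#' @param ampps Tibble `(ampp_id, amp_id, vmpp_id)`.
#' @param forms Tibble `(form_id, name)`, optional.
#' @return A `product_graph` (named list of tibbles).
#' @export
product_graph <- function(ingredients, vmps, vpi, amps, vmpps, ampps,
                          forms = tibble::tibble(form_id = character(),
                                                 name = character())) {
  as_chr <- function(df, cols) {
    df <- tibble::as_tibble(df)
    for (cl in intersect(cols, names(df))) df[[cl]] <- as.character(df[[cl]])
    df
  }
  g <- list(
    ingredients = as_chr(ingredients, c("ingredient_id")),
    vmps = as_chr(vmps, c("vmp_id", "form_id")),
    vpi = as_chr(vpi, c("vmp_id", "ingredient_id")),
    amps = as_chr(amps, c("amp_id", "vmp_id")),
    vmpps = as_chr(vmpps, c("vmpp_id", "vmp_id")),
    ampps = as_chr(ampps, c("ampp_id", "amp_id", "vmpp_id")),
    forms = as_chr(forms, c("form_id"))
  )
  g$vpi$strength_numerator_value <- as.numeric(g$vpi$strength_numerator_value)
  if (!"strength_denominator_value" %in% names(g$vpi)) {
    g$vpi$strength_denominator_value <- NA_real_
    g$vpi$strength_denominator_unit <- NA_character_
  } else {
    g$vpi$strength_denominator_value <-
      as.numeric(g$vpi$strength_denominator_value)
  }
  structure(g, class = "product_graph")
}

#' @export
print.product_graph <- function(x, ...) {
  cat("<product_graph>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Check referential integrity of a product graph
#'
#' Scans every cross-table link (AMP to VMP, VMPP to VMP, AMPP to AMP and
#' VMPP, ingredient-strength rows to VMP and ingredient) and every strength
#' positivity constraint. Violations are data, not exceptions: a well-formed
#' graph yields a zero-row tibble.
#'
#' @param graph A [product_graph()].
#' @return Tibble with columns `table`, `id`, `problem`; zero rows iff the
#'   graph is internally consistent.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "product_graph"))
  v <- list()
  dangling <- function(tab, ids, target, target_ids, link) {
    bad <- !ids %in% target_ids
    if (any(bad)) {
      tibble::tibble(
        table = tab,
        id = ids[bad],
        problem = paste0(link, " '", ids[bad], "' not found in ", target)
      )
    }
  }
  v[[1]] <- dangling("amp", graph$amps$vmp_id, "vmps", graph$vmps$vmp_id, "vmp_id")
  v[[2]] <- dangling("vmpp", graph$vmpps$vmp_id, "vmps", graph$vmps$vmp_id, "vmp_id")
  v[[3]] <- dangling("ampp", graph$ampps$amp_id, "amps", graph$amps$amp_id, "amp_id")
  v[[4]] <- dangling("ampp", graph$ampps$vmpp_id, "vmpps", graph$vmpps$vmpp_id, "vmpp_id")
  v[[5]] <- dangling("vpi", graph$vpi$vmp_id, "vmps", graph$vmps$vmp_id, "vmp_id")
  v[[6]] <- dangling("vpi", graph$vpi$ingredient_id, "ingredients",
                     graph$ingredients$ingredient_id, "ingredient_id")
  bad_strength <- is.na(graph$vpi$strength_numerator_value) |
    graph$vpi$strength_numerator_value <= 0
  if (any(bad_strength)) {
    v[[7]] <- tibble::tibble(
      table = "vpi",
      id = graph$vpi$vmp_id[bad_strength],
      problem = "strength_numerator_value not strictly positive"
    )
  }
  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0) {
    out <- tibble::tibble(table = character(), id = character(),
                          problem = character())
  }
  out
}

# unparenthesised ingredient-name stem: the grouping key for one API across
# its salt forms, e.g. "Amoxicillin (as amoxicillin trihydrate)" -> "Amoxicillin"
api_stem <- function(name) {
  stringr::str_trim(stringr::str_remove_all(name, "\\s*\\([^)]*\\)"))
}
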