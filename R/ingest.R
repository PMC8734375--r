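read_csv_chr <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

# name-based, order-insensitive, case-insensitive header match; hard error
# naming any missing required column
match_header <- function(df, required, internal, file) {
  have <- toupper(trimws(names(df)))
  idx <- match(toupper(required), have)
  if (anyNA(idx)) {
    stop("file '", file, "' is missing required column(s): ",
         paste(required[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- df[, idx, drop = FALSE]
  names(out) <- internal
  out
}

#' Read one monthly prescribing extract
#'
#' Reads a ten-column practice-level prescribing file (columns `SHA`, `PCT`,
#' `PRACTICE`, `BNF CODE`, `BNF NAME`, `ITEMS`, `NIC`, `ACT COST`,
#' `QUANTITY`, `PERIOD`; any column order, matched by name). Every row is
#' either accepted as a typed prescription record or routed to the reject log
#' with a reason — `nrow(records) + nrow(rejects)` always equals the number
#' of input rows.
#'
#' @param path Path to a CSV file in the extract dialect.
#' @return List with `records` (tibble: `sha`, `pct`, `practice`, `bnf_code`,
#'   `bnf_name`, `items`, `nic`, `act_cost`, `quantity`, `period`) and
#'   `rejects` (raw fields plus `reason`).
#' @export
read_prescriptions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- match_header(read_csv_chr(path), pdpi_columns, pdpi_internal, path)
  if (nrow(raw) == 0) {
    warning("empty prescription file: ", path, call. = FALSE)
  }
  validate_prescription_rows(raw)
}

#' Write prescription records in the extract dialect
#'
#' Inverse of [read_prescriptions()]: records accepted by the validator
#' round-trip through write-then-read identically on all ten fields.
#'
#' @param records Tibble of prescription records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prescriptions <- function(records, path) {
  out <- records[, pdpi_internal]
  names(out) <- pdpi_columns
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Combine monthly prescribing extracts from a directory
#'
#' Reads every matching file, concatenates accepted records with a
#' `source_file` provenance column, and pools the per-file reject logs.
#' Duplicate rows across files are retained; provenance distinguishes them.
#'
#' @param directory Directory containing monthly extract CSVs.
#' @param pattern Filename regular expression selecting extract files.
#' @return List with `records`, `rejects` (both carrying `source_file`) and
#'   `file_counts` (per-file accepted/rejected row counts).
#' @export
combine_monthly <- function(directory, pattern = "\\.csv$") {
  files <- sort(list.files(directory, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) {
    stop("no prescription files matching '", pattern, "' in ", directory,
         call. = FALSE)
  }
  parts <- lapply(files, function(f) {
    r <- read_prescriptions(f)
    r$records$source_file <- basename(f)
    if (nrow(r$rejects) > 0) r$rejects$source_file <- basename(f)
    r
  })
  list(
    records = dplyr::bind_rows(lapply(parts, `[[`, "records")),
    rejects = dplyr::bind_rows(lapply(parts, `[[`, "rejects")),
    file_counts = tibble::tibble(
      file = basename(files),
      accepted = vapply(parts, function(p) nrow(p$records), integer(1)),
      rejected = vapply(parts, function(p) nrow(p$rejects), integer(1))
    )
  )
}

#' Read a BNF to SNOMED mapping table
#'
#' Expects columns `bnf_code`, `snomed_code`, `description` (order and case
#' insensitive). SNOMED codes must be purely numeric strings; other rows are
#' rejected with a reason. Duplicate `(bnf_code, snomed_code)` pairs are
#' collapsed and the number of collapsed rows reported.
#'
#' @param path CSV path.
#' @return List with `map` (deduplicated tibble), `rejects`, and
#'   `n_duplicates` (count of collapsed duplicate pairs).
#' @export
read_snomed_map <- function(path) {
  raw <- match_header(read_csv_chr(path),
                      c("BNF_CODE", "SNOMED_CODE", "DESCRIPTION"),
                      c("bnf_code", "snomed_code", "description"), path)
  raw$bnf_code <- normalise_bnf_code(raw$bnf_code)
  raw$snomed_code <- stringr::str_trim(raw$snomed_code)
  bad <- is.na(raw$snomed_code) | !grepl("^[0-9]+$", raw$snomed_code)
  rejects <- dplyr::mutate(raw[bad, , drop = FALSE],
                           reason = "snomed_code not numeric")
  ok <- raw[!bad, , drop = FALSE]
  deduped <- dplyr::distinct(ok, .data$bnf_code, .data$snomed_code,
                             .keep_all = TRUE)
  list(map = deduped, rejects = rejects,
       n_duplicates = nrow(ok) - nrow(deduped))
}

#' Read dm+d-style hierarchy tables into a product graph
#'
#' Loads the six canonical tables (`ingredient`, `vmp`, `vpi`, `amp`, `vmpp`,
#' `ampp`; `form` optional) from CSV files named `<table>.csv` under
#' `directory`. Ingredient-strength rows with a non-positive numerator are
#' rejected and logged. The assembled graph is integrity-checked; any
#' violations are returned alongside, never raised.
#'
#' @param directory Directory holding the table CSVs.
#' @return List with `graph` (a [product_graph()]), `rejects` (dropped vpi
#'   rows with `reason`) and `violations` (result of [validate_graph()]).
#' @export
read_dmd <- function(directory) {
  need <- c("ingredient", "vmp", "vpi", "amp", "vmpp", "ampp")
  paths <- file.path(directory, paste0(need, ".csv"))
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing dm+d table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tabs <- lapply(paths, read_csv_chr)
  names(tabs) <- need
  form_path <- file.path(directory, "form.csv")
  forms <- if (file.exists(form_path)) read_csv_chr(form_path) else
    tibble::tibble(form_id = character(), name = character())

  vpi <- tabs$vpi
  vpi$strength_numerator_value <-
    suppressWarnings(as.numeric(vpi$strength_numerator_value))
  bad <- is.na(vpi$strength_numerator_value) |
    vpi$strength_numerator_value <= 0
  rejects <- dplyr::mutate(vpi[bad, , drop = FALSE],
                           reason = "strength_numerator_value not strictly positive")
  graph <- product_graph(
    ingredients = tabs$ingredient,
    vmps = tabs$vmp,
    vpi = vpi[!bad, , drop = FALSE],
    amps = tabs$amp,
    vmpps = tabs$vmpp,
    ampps = tabs$ampp,
    forms = forms
  )
  list(graph = graph, rejects = rejects, violations = validate_graph(graph))
}

#' Read and combine practice address files
#'
#' ADDR files carry columns `PERIOD`, `PRACTICE`, `NAME`, `ADDRESS`,
#' `POSTCODE` (order and case insensitive). One directory row is kept per
#' practice code; when postcodes conflict across source periods the latest
#' period wins and the superseded values are logged.
#'
#' @param addr_paths Character vector of ADDR CSV paths.
#' @return List with `practices` (tibble: `practice`, `name`, `address`,
#'   `postcode`, `period`) and `conflicts` (superseded rows).
#' @export
read_practices <- function(addr_paths) {
  parts <- lapply(addr_paths, function(p) {
    match_header(read_csv_chr(p),
                 c("PERIOD", "PRACTICE", "NAME", "ADDRESS", "POSTCODE"),
                 c("period", "practice", "name", "address", "postcode"), p)
  })
  all_rows <- dplyr::distinct(dplyr::bind_rows(parts))
  if (nrow(all_rows) == 0) {
    return(list(practices = all_rows, conflicts = all_rows))
  }
  all_rows <- dplyr::arrange(all_rows, .data$practice, dplyr::desc(.data$period))
  latest <- dplyr::slice_head(dplyr::group_by(all_rows, .data$practice), n = 1)
  latest <- dplyr::ungroup(latest)
  superseded <- dplyr::anti_join(all_rows, latest, by = c("practice", "period"))
  conflicts <- dplyr::filter(
    dplyr::left_join(superseded,
                     dplyr::select(latest, "practice", winning_postcode = "postcode"),
                     by = "practice"),
    .data$postcode != .data$winning_postcode
  )
  list(
    practices = latest[, c("practice", "name", "address", "postcode", "period")],
    conflicts = conflicts
  )
}

#' Read a postcode-to-coordinates lookup
#'
#' Three-column CSV (`pcds`, `long`, `lat`), the National Statistics Postcode
#' Lookup subset. Postcodes are normalised (upper case, single internal
#' space) and deduplicated, first occurrence winning.
#'
#' @param path CSV path.
#' @return Tibble with `postcode`, `lon`, `lat`.
#' @export
read_postcode_lookup <- function(path) {
  raw <- match_header(read_csv_chr(path), c("PCDS", "LONG", "LAT"),
                      c("postcode", "lon", "lat"), path)
  raw$postcode <- normalise_postcode(raw$postcode)
  raw$lon <- as.numeric(raw$lon)
  raw$lat <- as.numeric(raw$lat)
  dplyr::distinct(raw, .data$postcode, .keep_all = TRUE)
}
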