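# Fixture builders and independent oracles shared across the suite.

# The five worked-example rows of the monthly extract dialect.
table1_records <- function() {
  tibble::tribble(
    ~sha,  ~pct,  ~practice, ~bnf_code,         ~bnf_name,                ~items, ~nic,  ~act_cost, ~quantity, ~period,
    "Q44", "RTV", "Y04937",  "0304010W0BBABAL", "Phenergan_Tab 25 mg",    3L,     8.15,  7.89,      98,        "201801",
    "Q44", "RTV", "Y04937",  "0401010Z0AAAAAA", "Zopiclone_Tab 7.5 mg",   7L,     2.88,  3.35,      98,        "201801",
    "Q44", "RTV", "Y04937",  "0401020K0AAAHAH", "Diazepam_Tab 2 mg",      5L,     3.76,  3.94,      191,       "201801",
    "Q44", "RTV", "Y04937",  "0402010ADAAAAAA", "Aripiprazole_Tab 10 mg", 3L,     13.64, 12.88,     63,        "201801",
    "Q44", "RTV", "Y04937",  "0402010ADAAADAD", "Aripiprazole_Tab 5 mg",  1L,     1.36,  1.37,      7,         "201801"
  )
}

write_table1_csv <- function(path = tempfile(fileext = ".csv")) {
  write_prescriptions(table1_records(), path)
  path
}

# Single-ingredient toy: one VMP "Drug A 500 mg capsules", 3 AMPs, 2 VMPPs
# (and their AMPPs), one BNF code.
toy_graph_single <- function() {
  product_graph(
    ingredients = tibble::tibble(ingredient_id = "9001", name = "Drug A"),
    vmps = tibble::tibble(vmp_id = "100", name = "Drug A 500mg capsules",
                          form_id = "F1"),
    vpi = tibble::tibble(vmp_id = "100", ingredient_id = "9001",
                         strength_numerator_value = 500,
                         strength_numerator_unit = "mg",
                         strength_denominator_value = NA_real_,
                         strength_denominator_unit = NA_character_),
    amps = tibble::tibble(amp_id = c("201", "202", "203"), vmp_id = "100",
                          name = paste("Brand", 1:3), supplier = paste("S", 1:3)),
    vmpps = tibble::tibble(vmpp_id = c("301", "302"), vmp_id = "100",
                           pack_size = c(28, 100), pack_unit = "capsule"),
    ampps = tibble::tibble(ampp_id = c("401", "402", "403"),
                           amp_id = c("201", "202", "203"),
                           vmpp_id = c("301", "301", "302")),
    forms = tibble::tibble(form_id = "F1", name = "capsule")
  )
}

toy_map_single <- function() {
  tibble::tibble(
    bnf_code = "050101000AAABAB",
    snomed_code = c("201", "301", "401", "402"),
    description = "Drug A_Cap 500 mg"
  )
}

# Two-ingredient toy mirroring a 500 mg / 125 mg combination tablet.
toy_graph_combo <- function() {
  product_graph(
    ingredients = tibble::tibble(
      ingredient_id = c("9001", "9002"),
      name = c("Amoxibest (as amoxibest trihydrate)",
               "Clavulin (as potassium clavulin)")
    ),
    vmps = tibble::tibble(vmp_id = "100",
                          name = "Amoxibest/Clavulin 500mg/125mg tablets",
                          form_id = "F1"),
    vpi = tibble::tibble(vmp_id = "100", ingredient_id = c("9001", "9002"),
                         strength_numerator_value = c(500, 125),
                         strength_numerator_unit = "mg",
                         strength_denominator_value = NA_real_,
                         strength_denominator_unit = NA_character_),
    amps = tibble::tibble(amp_id = "201", vmp_id = "100",
                          name = "Combo brand", supplier = "S1"),
    vmpps = tibble::tibble(vmpp_id = c("301", "302"), vmp_id = "100",
                           pack_size = c(21, 100), pack_unit = "tablet"),
    ampps = tibble::tibble(ampp_id = "401", amp_id = "201", vmpp_id = "301"),
    forms = tibble::tibble(form_id = "F1", name = "tablet")
  )
}

toy_map_combo <- function() {
  tibble::tibble(
    bnf_code = "050101100AAACAC",
    snomed_code = c("201", "301", "401"),
    description = "Amoxibest/Clavulin_Tab 500 mg/125 mg"
  )
}

# Independent brute-force catalog oracle: walks every resolution path by
# explicit loops and table scans, no joins, mirroring none of the package's
# internals. Returns rows sorted for comparison.
brute_force_catalog <- function(map, graph) {
  rows <- list()
  for (i in seq_len(nrow(map))) {
    code <- map$snomed_code[i]
    vmp <- NULL
    provenance <- NULL
    if (code %in% graph$amps$amp_id) {
      provenance <- "AMP"
      vmp <- graph$amps$vmp_id[graph$amps$amp_id == code][1]
    } else if (code %in% graph$vmps$vmp_id) {
      provenance <- "VMP"
      vmp <- code
    } else if (code %in% graph$vmpps$vmpp_id) {
      provenance <- "VMPP"
      vmp <- graph$vmpps$vmp_id[graph$vmpps$vmpp_id == code][1]
    } else if (code %in% graph$ampps$ampp_id) {
      provenance <- "AMPP"
      amp <- graph$ampps$amp_id[graph$ampps$ampp_id == code][1]
      vmp <- graph$amps$vmp_id[graph$amps$amp_id == amp][1]
    }
    if (is.null(vmp)) next
    form_id <- graph$vmps$form_id[graph$vmps$vmp_id == vmp][1]
    form <- graph$forms$name[graph$forms$form_id == form_id]
    form <- if (length(form) == 0) NA_character_ else form[1]
    for (j in which(graph$vpi$vmp_id == vmp)) {
      ing <- graph$vpi$ingredient_id[j]
      api_name <- graph$ingredients$name[graph$ingredients$ingredient_id == ing][1]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        bnf_code = map$bnf_code[i],
        api_name = api_name,
        api = trimws(gsub("\\s*\\([^)]*\\)", "", api_name)),
        strength_value = graph$vpi$strength_numerator_value[j],
        strength_unit = graph$vpi$strength_numerator_unit[j],
        denominator_value = graph$vpi$strength_denominator_value[j],
        denominator_unit = graph$vpi$strength_denominator_unit[j],
        form = form,
        provenance = provenance
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  # dedupe identical components keeping highest-precedence provenance
  out$provenance <- factor(out$provenance,
                           levels = c("AMP", "VMP", "VMPP", "AMPP"))
  out <- out[order(out$bnf_code, out$api, out$provenance), ]
  key <- paste(out$bnf_code, out$api, out$api_name, out$strength_value,
               out$strength_unit, out$denominator_value,
               out$denominator_unit, out$form, sep = "\r")
  out <- out[!duplicated(key), ]
  # ambiguity: >1 surviving variant for a (bnf_code, api) pair
  grp <- paste(out$bnf_code, out$api, sep = "\r")
  out$ambiguous <- as.vector(table(grp)[grp] > 1)
  out$provenance <- as.character(out$provenance)
  out[order(out$bnf_code, out$api, out$strength_value), ]
}

# Independent winding-number containment oracle (nonzero rule). Points on an
# edge are not well defined under this oracle; test points avoid edges.
winding_number_inside <- function(px, py, ring) {
  wn <- 0L
  for (i in seq_len(nrow(ring) - 1L)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    is_left <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    if (y1 <= py) {
      if (y2 > py && is_left > 0) wn <- wn + 1L
    } else {
      if (y2 <= py && is_left < 0) wn <- wn - 1L
    }
  }
  wn != 0L
}

# small fixture config used across tests to keep runtimes tight
small_config <- function(seed = 11) {
  fixture_config(seed = seed, n_practices = 4, n_months = 3, n_apis = 3,
                 products_per_api = 3)
}
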