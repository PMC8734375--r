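test_that("resolution tries product levels before pack levels", {
  g <- toy_graph_single()
  r <- resolve_snomed("201", g)
  expect_equal(r$level, "AMP")
  expect_equal(r$vmp_id, "100")

  r <- resolve_snomed("100", g)
  expect_equal(r$level, "VMP")

  r <- resolve_snomed("301", g)   # VMPP-only id, traversed up
  expect_equal(r$level, "VMPP")
  expect_equal(r$vmp_id, "100")
  expect_equal(r$pack$size, 28)

  r <- resolve_snomed("401", g)   # AMPP id, traversed via its AMP
  expect_equal(r$level, "AMPP")
  expect_equal(r$vmp_id, "100")

  r <- resolve_snomed("999999", g)
  expect_equal(r$level, "unresolved")
  expect_true(is.na(r$vmp_id))
})

test_that("an id present at several levels resolves at the highest precedence", {
  g <- toy_graph_single()
  g$vmpps$vmpp_id[1] <- "201"  # same id as an AMP
  expect_equal(resolve_snomed("201", g)$level, "AMP")
})

test_that("a single-ingredient product yields one catalog component", {
  built <- build_bnf_catalog(toy_map_single(), toy_graph_single())
  expect_equal(nrow(built$catalog), 1)
  expect_equal(built$catalog$api, "Drug A")
  expect_equal(built$catalog$strength_value, 500)
  expect_equal(built$catalog$strength_unit, "mg")
  expect_equal(built$catalog$form, "capsule")
  expect_equal(built$catalog$provenance, "AMP")  # deduped to best provenance
  expect_false(built$catalog$ambiguous)
  expect_equal(nrow(built$unresolved), 0)
  expect_equal(built$match_rate, 1)
})

test_that("a two-ingredient product yields two components under one code", {
  built <- build_bnf_catalog(toy_map_combo(), toy_graph_combo())
  expect_equal(nrow(built$catalog), 2)
  expect_equal(unique(built$catalog$bnf_code), "050101100AAACAC")
  expect_equal(sort(built$catalog$strength_value), c(125, 500))
  expect_equal(built$catalog$api, c("Amoxibest", "Clavulin"))
  # salt qualifiers stay in the display name, not the grouping key
  expect_match(built$catalog$api_name[1], "trihydrate")
  expect_false(any(built$catalog$ambiguous))
})

test_that("disagreeing strengths are kept and flagged ambiguous, not averaged", {
  g <- toy_graph_single()
  # second VMP with a different strength for the same ingredient
  g$vmps <- dplyr::bind_rows(g$vmps, tibble::tibble(
    vmp_id = "101", name = "Drug A 250mg capsules", form_id = "F1"))
  g$vpi <- dplyr::bind_rows(g$vpi, tibble::tibble(
    vmp_id = "101", ingredient_id = "9001",
    strength_numerator_value = 250, strength_numerator_unit = "mg",
    strength_denominator_value = NA_real_,
    strength_denominator_unit = NA_character_))
  map <- dplyr::bind_rows(toy_map_single(), tibble::tibble(
    bnf_code = "050101000AAABAB", snomed_code = "101",
    description = "Drug A_Cap 250 mg"))
  built <- build_bnf_catalog(map, g)
  expect_equal(nrow(built$catalog), 2)
  expect_true(all(built$catalog$ambiguous))
  expect_setequal(built$catalog$strength_value, c(250, 500))
})

test_that("catalog construction is independent of mapping row order", {
  map <- toy_map_single()
  built1 <- build_bnf_catalog(map, toy_graph_single())
  built2 <- build_bnf_catalog(map[rev(seq_len(nrow(map))), ], toy_graph_single())
  expect_equal(built1$catalog, built2$catalog)
})

test_that("unresolved codes are reported with the match rate", {
  map <- dplyr::bind_rows(toy_map_single(), tibble::tibble(
    bnf_code = "999999999AAAAAA", snomed_code = "31415926",
    description = "Ghost_Tab 1 mg"))
  built <- build_bnf_catalog(map, toy_graph_single())
  expect_equal(nrow(built$unresolved), 1)
  expect_equal(built$unresolved$snomed_code, "31415926")
  expect_equal(built$match_rate, 0.5)
  empty <- build_bnf_catalog(map[0, ], toy_graph_single())
  expect_equal(nrow(empty$catalog), 0)
  expect_equal(nrow(empty$unresolved), 0)
})

test_that("catalog equals an exhaustive brute-force walk on toy graphs", {
  for (case in list(list(m = toy_map_single(), g = toy_graph_single()),
                    list(m = toy_map_combo(), g = toy_graph_combo()))) {
    built <- build_bnf_catalog(case$m, case$g)
    oracle <- brute_force_catalog(case$m, case$g)
    got <- built$catalog[, names(oracle)]
    expect_equal(as.data.frame(got), as.data.frame(oracle),
                 ignore_attr = TRUE)
  }
})

test_that("catalog equals the brute-force walk on a generated fixture graph", {
  dir <- withr::local_tempdir()
  generate_fixture(small_config(), dir)
  dmd <- read_dmd(dir = file.path(dir, "dmd"))
  expect_equal(nrow(dmd$violations), 0)
  map <- read_snomed_map(file.path(dir, "snomed_map.csv"))$map
  built <- build_bnf_catalog(map, dmd$graph)
  oracle <- brute_force_catalog(map, dmd$graph)
  got <- built$catalog[, names(oracle)]
  expect_equal(as.data.frame(got), as.data.frame(oracle), ignore_attr = TRUE)
})

test_that("product descriptions parse stem, form token and trailing strength", {
  p <- parse_product_description(c(
    "Phenergan_Tab 25 mg",
    "Zopiclone_Tab 7.5 mg",
    "Sod Chlor_Irrig Soln",
    "Clarithromycin_I/V Inf 500 mg Vl",
    "Aripiprazole_Tab 10 mg"
  ))
  expect_equal(p$stem, c("Phenergan", "Zopiclone", "Sod Chlor",
                         "Clarithromycin", "Aripiprazole"))
  expect_equal(p$form_token[1:2], c("Tab", "Tab"))
  expect_equal(p$form_token[3], "Irrig Soln")
  expect_equal(p$form_token[4], "I/V Inf")
  expect_equal(p$strength_value, c(25, 7.5, NA, 500, 10))
  expect_equal(p$strength_unit, c("mg", "mg", NA, "mg", "mg"))
})

test_that("exclusion rules partition the catalog and name the matching rule", {
  catalog <- tibble::tibble(
    bnf_code = sprintf("%015d", 1:4),
    api_name = c("A", "B", "C", "D"), api = c("A", "B", "C", "D"),
    strength_value = 1, strength_unit = "mg",
    denominator_value = NA_real_, denominator_unit = NA_character_,
    form = c("bath additive", "capsule", "tablet", "cutaneous spray"),
    provenance = "AMP",
    description = c("Oilatum_Bath Additive", "Multivitamin_Cap",
                    "Diazepam_Tab 2 mg", "Beclomet_Spray"),
    ambiguous = FALSE
  )
  res <- apply_exclusions(catalog)
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(catalog))
  expect_equal(res$kept$api, "C")  # the plain tablet survives
  expect_equal(res$excluded$rule[res$excluded$api == "A"], "bath additive")
  expect_equal(res$excluded$rule[res$excluded$api == "B"], "multivitamin")
  expect_equal(res$excluded$rule[res$excluded$api == "D"], "spray")
})

test_that("resolution levels partition all SNOMED codes", {
  dir <- withr::local_tempdir()
  generate_fixture(small_config(), dir)
  g <- read_dmd(file.path(dir, "dmd"))$graph
  map <- read_snomed_map(file.path(dir, "snomed_map.csv"))$map
  codes <- c(map$snomed_code, "55555555")
  levels <- vapply(codes, function(cc) resolve_snomed(cc, g)$level, character(1))
  expect_true(all(levels %in% c("AMP", "VMP", "VMPP", "AMPP", "unresolved")))
  expect_equal(sum(levels == "unresolved"), 1)
})
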