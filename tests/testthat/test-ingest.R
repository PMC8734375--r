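test_that("the worked-example extract parses to five records and no rejects", {
  path <- write_table1_csv()
  res <- read_prescriptions(path)
  expect_equal(nrow(res$records), 5)
  expect_equal(nrow(res$rejects), 0)
  expect_equal(res$records$quantity, c(98, 98, 191, 63, 7))
  expect_equal(res$records$bnf_name[1], "Phenergan_Tab 25 mg")
  expect_true(all(nchar(res$records$bnf_code) == 15))
})

test_that("a header-only file yields zero records with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("SHA,PCT,PRACTICE,BNF CODE,BNF NAME,ITEMS,NIC,ACT COST,QUANTITY,PERIOD",
             path)
  expect_warning(res <- read_prescriptions(path), "empty")
  expect_equal(nrow(res$records), 0)
})

test_that("malformed rows go to the reject log with reasons, never dropped", {
  recs <- table1_records()
  recs$period[2] <- "201813"          # month out of range
  recs$bnf_code[3] <- "SHORTCODE"     # not 15 characters
  recs$quantity[4] <- -5              # negative
  path <- withr::local_tempfile(fileext = ".csv")
  write_prescriptions(recs, path)
  res <- read_prescriptions(path)
  expect_equal(nrow(res$records) + nrow(res$rejects), 5)
  expect_equal(nrow(res$rejects), 3)
  expect_setequal(res$rejects$reason,
                  c("period not a valid YYYYMM", "bnf_code not 15 characters",
                    "quantity negative"))
})

test_that("a missing required column is a hard error naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SHA,PCT,PRACTICE,BNF CODE,ITEMS,NIC,ACT COST,QUANTITY,PERIOD",
               "Q44,RTV,Y04937,0304010W0BBABAL,3,8.15,7.89,98,201801"), path)
  expect_error(read_prescriptions(path), "BNF NAME")
})

test_that("column order does not matter for the reader", {
  recs <- table1_records()
  path <- withr::local_tempfile(fileext = ".csv")
  out <- recs[, rev(names(recs))]
  names(out) <- rev(c("SHA", "PCT", "PRACTICE", "BNF CODE", "BNF NAME",
                      "ITEMS", "NIC", "ACT COST", "QUANTITY", "PERIOD"))
  readr::write_csv(out, path)
  res <- read_prescriptions(path)
  expect_equal(res$records, recs)
})

test_that("combine_monthly adds counts and keeps duplicates with provenance", {
  dir <- withr::local_tempdir()
  r <- table1_records()
  write_prescriptions(r, file.path(dir, "PDPI_201801.csv"))
  write_prescriptions(r[1:2, ], file.path(dir, "PDPI_201802.csv"))
  write_prescriptions(r[1:2, ], file.path(dir, "PDPI_201803.csv"))
  res <- combine_monthly(dir)
  expect_equal(nrow(res$records), 9)
  expect_equal(res$file_counts$accepted, c(5L, 2L, 2L))
  # identical rows from different files are distinguished by source_file
  dup <- dplyr::filter(res$records, .data$bnf_code == r$bnf_code[1])
  expect_equal(sort(unique(dup$source_file)),
               c("PDPI_201801.csv", "PDPI_201802.csv", "PDPI_201803.csv"))
  expect_error(combine_monthly(withr::local_tempdir()), "no prescription files")
})

test_that("combining shuffled file sets yields the same row multiset", {
  dir <- withr::local_tempdir()
  r <- table1_records()
  write_prescriptions(r[1:3, ], file.path(dir, "b.csv"))
  write_prescriptions(r[4:5, ], file.path(dir, "a.csv"))
  res <- combine_monthly(dir)
  key <- sort(paste(res$records$bnf_code, res$records$quantity))
  expect_equal(key, sort(paste(r$bnf_code, r$quantity)))
})

test_that("the printed mapping-table rows load with the expected multiplicity", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "bnf_code,snomed_code,description",
    "'0501050B0BEAAAE',18149311000001103,Clarie XL_Tab 500 mg",
    "'0501050B0BEAAAE',18149411000001105,Clarie XL_Tab 500 mg",
    "'0501050B0AAACAC',34751711000001107,Clarithromycin_I/V Inf 500 mg Vl",
    "'0501050B0AAACAC',13469811000001104,Clarithromycin_I/V Inf 500 mg Vl",
    "'0501050B0AAACAC',17997811000001100,Clarithromycin_I/V Inf 500 mg Vl",
    "'0501050B0AAACAC',13613011000001105,Clarithromycin_I/V Inf 500 mg Vl"
  ), path)
  res <- read_snomed_map(path)
  expect_equal(nrow(res$map), 6)
  expect_equal(sum(res$map$bnf_code == "0501050B0AAACAC"), 4)
  expect_equal(res$n_duplicates, 0)
})

test_that("duplicate mapping pairs collapse and non-numeric codes reject", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bnf_code,snomed_code,description",
               "0501050B0BEAAAE,181493,X",
               "0501050B0BEAAAE,181493,X",
               "0501050B0BEAAAE,notacode,X"), path)
  res <- read_snomed_map(path)
  expect_equal(nrow(res$map), 1)
  expect_equal(res$n_duplicates, 1)
  expect_equal(res$rejects$reason, "snomed_code not numeric")
})

test_that("dm+d reading rejects non-positive strengths and names missing tables", {
  dir <- withr::local_tempdir()
  g <- toy_graph_single()
  tabs <- list(ingredient = g$ingredients, vmp = g$vmps, vpi = g$vpi,
               amp = g$amps, vmpp = g$vmpps, ampp = g$ampps, form = g$forms)
  tabs$vpi <- dplyr::bind_rows(
    tabs$vpi,
    dplyr::mutate(tabs$vpi, strength_numerator_value = 0)
  )
  for (nm in names(tabs)) {
    readr::write_csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  res <- read_dmd(dir)
  expect_equal(nrow(res$rejects), 1)
  expect_equal(nrow(res$violations), 0)
  expect_equal(nrow(res$graph$vpi), 1)
  file.remove(file.path(dir, "vmpp.csv"))
  expect_error(read_dmd(dir), "vmpp")
})

test_that("practice directory keeps the latest postcode and logs conflicts", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("PERIOD,PRACTICE,NAME,ADDRESS,POSTCODE",
               "201801,P1,Alpha,1 High St,BA1 1AA",
               "201801,P2,Beta,2 Low St,BA2 2BB"), p1)
  writeLines(c("PERIOD,PRACTICE,NAME,ADDRESS,POSTCODE",
               "201806,P1,Alpha,9 New St,BA9 9ZZ",
               "201806,P2,Beta,2 Low St,BA2 2BB"), p2)
  res <- read_practices(c(p1, p2))
  expect_equal(nrow(res$practices), 2)
  expect_equal(res$practices$postcode[res$practices$practice == "P1"], "BA9 9ZZ")
  expect_equal(res$conflicts$practice, "P1")
  expect_equal(res$conflicts$postcode, "BA1 1AA")
})

test_that("unit table reading applies definitional factors and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit,kind,factor_to_kg",
               "mg,mass,1e-6",
               "microgram,mass,1e-9",
               "badunit,mass,-1",
               "ml,volume,",
               "stone,weight,6.35"), path)
  res <- read_unit_table(path)
  expect_equal(unit_to_kg(1, "mg", res$units), 1e-6)
  expect_equal(unit_to_kg(1, "microgram", res$units), 1e-9)
  expect_equal(nrow(res$rejects), 2)
  expect_match(res$rejects$reason[1], "positive")
  expect_match(res$rejects$reason[2], "unknown unit kind")
})
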