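test_that("read_inventory parses a valid file and validates invariants", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scheme_id,provider,indication,techniques,scope_technique,scope_genotyping,scope_interpretation,modality,fee_eur,offered_years",
    "S1,EMQN,cystic fibrosis,sequencing;mlpa,1,1,1,wet,1200,",
    "S2,GenQA,fragile x syndrome,fragment_analysis,0,0,1,virtual,300.50,2024;2025"),
    f)
  inv <- read_inventory(f)
  expect_s3_class(inv, "eqa_inventory")
  expect_equal(nrow(inv), 2)
  expect_equal(inv$techniques[[1]], c("sequencing", "mlpa"))
  expect_equal(inv$offered_years[[2]], c(2024L, 2025L))
  expect_equal(inv$fee_cents, c(120000L, 30050L))

  # all scope flags 0 violates the at-least-one-aspect invariant
  writeLines(c(
    "scheme_id,provider,indication,techniques,scope_technique,scope_genotyping,scope_interpretation,modality,fee_eur,offered_years",
    "S1,EMQN,cystic fibrosis,sequencing,0,0,0,wet,1200,"), f)
  expect_error(read_inventory(f), "scope flags")

  # malformed cell errors name row and column
  writeLines(c(
    "scheme_id,provider,indication,techniques,scope_technique,scope_genotyping,scope_interpretation,modality,fee_eur,offered_years",
    "S1,EMQN,cystic fibrosis,sequencing,1,1,1,wet,not_money,"), f)
  expect_error(read_inventory(f), "row 1.*fee_eur")

  # duplicate ids are rejected by name
  writeLines(c(
    "scheme_id,provider,indication,techniques,scope_technique,scope_genotyping,scope_interpretation,modality,fee_eur,offered_years",
    "S1,EMQN,cystic fibrosis,sequencing,1,1,1,wet,100,",
    "S1,GenQA,cystic fibrosis,sequencing,1,1,1,wet,100,"), f)
  expect_error(read_inventory(f), "duplicate scheme_id: S1")
})

test_that("inventory round-trips byte-identically through write/read", {
  inv <- generate_inventory(small_cfg(1))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_inventory(inv, f1)
  inv2 <- read_inventory(f1)
  write_inventory(inv2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(inv2$fee_cents, inv$fee_cents)
  expect_equal(inv2$techniques, inv$techniques)
})

test_that("classify_scope is total and injective on valid flag triples", {
  flags <- expand.grid(t = c(TRUE, FALSE), g = c(TRUE, FALSE),
                       i = c(TRUE, FALSE))
  flags <- flags[rowSums(flags) > 0, ]
  inv <- new_inventory(sprintf("S%d", seq_len(nrow(flags))), "P", "x",
                       rep(list("tech"), nrow(flags)),
                       flags$t, flags$g, flags$i, "wet",
                       rep(0L, nrow(flags)))
  cats <- classify_scope(inv)
  expect_length(unique(cats), nrow(flags))   # injective
  expect_true(all(cats %in% c("TGI", "TG", "GI", "TI", "T", "G", "I")))
  expect_equal(classify_scope(inv[inv$scope_technique & inv$scope_genotyping &
                                    inv$scope_interpretation, ]), "TGI")
  expect_equal(classify_scope(inv[inv$scope_technique & inv$scope_genotyping &
                                    !inv$scope_interpretation, ]), "TG")
  expect_equal(classify_scope(inv[!inv$scope_technique & !inv$scope_genotyping &
                                    inv$scope_interpretation, ]), "I")
})

test_that("scope_summary counts sum to inventory size and rounds percents", {
  one <- micro_scheme("S1", "x", "sequencing")
  s <- scope_summary(one)
  expect_equal(s$category, "TGI")
  expect_equal(s$count, 1L)
  expect_equal(s$pct, 100L)

  four <- new_inventory(c("A", "B", "C", "D"), "P", "x",
                        rep(list("tech"), 4),
                        c(TRUE, FALSE, FALSE, TRUE),
                        c(FALSE, TRUE, FALSE, TRUE),
                        c(FALSE, FALSE, TRUE, FALSE),
                        "wet", rep(0L, 4))
  s4 <- scope_summary(four)
  expect_setequal(s4$category, c("T", "G", "I", "TG"))
  expect_true(all(s4$pct == 25L))
  expect_equal(sum(s4$count), 4L)

  expect_error(scope_summary(one[0, ]), "non-empty")
})

test_that("center profiles round-trip through YAML and enforce invariants", {
  ctr <- one_tech_center()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_center(ctr, f)
  ctr2 <- read_center(f)
  expect_equal(ctr2$center_id, ctr$center_id)
  expect_equal(ctr2$techniques$validation_date, ctr$techniques$validation_date)
  expect_equal(ctr2$indications$techniques_used,
               ctr$indications$techniques_used)

  # indication referencing an unknown technique is rejected
  tech <- data.frame(technique_id = "sequencing",
                     validation_date = as.Date("2015-01-01"),
                     method_class = "in_house", annual_volume = 10L)
  ind <- data.frame(indication = "x", annual_requests = 1L)
  ind$techniques_used <- list("mlpa")
  expect_error(new_center("C1", tech, ind), "unknown technique")

  # method change cannot predate validation
  tech$last_method_change <- as.Date("2014-01-01")
  ind$techniques_used <- list("sequencing")
  expect_error(new_center("C1", tech, ind), "predates")
})

test_that("histories validate outcomes and year range and round-trip", {
  expect_error(new_history("C1", "S1", 1901L, "satisfactory", TRUE),
               "plausible range")
  expect_error(new_history("C1", "S1", 2020L, "oops", TRUE), "outcome")
  h <- new_history(c("C1", "C1"), c("S1", "S2"), c(2020L, 2021L),
                   c("satisfactory", "genotyping_error"), c(TRUE, FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_history(h, f)
  expect_equal(read_history(f), h)
})
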