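test_that("derive_requirements applies the triennial exemption rules", {
  # well-validated, high-volume, unchanged -> triennial exemption
  r <- derive_requirements(one_tech_center("2019-01-01", 400L), 2024, 297)
  tech <- r[r$aspect == "technique_coverage", ]
  expect_equal(tech$period, "triennial")
  expect_equal(tech$reason, "S1-exemption")
  expect_true(tech$exemption_documented)

  # volume below the threshold -> annual
  r <- derive_requirements(one_tech_center("2019-01-01", 100L), 2024, 297)
  expect_equal(r$period[r$aspect == "technique_coverage"], "annual")

  # validated too recently -> annual even at high volume
  r <- derive_requirements(one_tech_center("2023-01-01", 1000L), 2024, 297)
  expect_equal(r$period[r$aspect == "technique_coverage"], "annual")

  # "more than 3 years" is strict at January 1 of the plan year
  r <- derive_requirements(one_tech_center("2021-01-01", 400L), 2024, 297)
  expect_equal(r$period[r$aspect == "technique_coverage"], "annual")
  r <- derive_requirements(one_tech_center("2020-12-31", 400L), 2024, 297)
  expect_equal(r$period[r$aspect == "technique_coverage"], "triennial")

  # a method change within 3 years cancels the exemption
  r <- derive_requirements(one_tech_center("2015-01-01", 400L,
                                           change = "2022-06-01"), 2024, 297)
  expect_equal(r$period[r$aspect == "technique_coverage"], "annual")

  # every indication gets a triennial genotyping/interpretation requirement
  gi <- r[r$aspect == "genotyping_interpretation", ]
  expect_equal(gi$period, "triennial")
  expect_equal(gi$reason, "S2")
})

test_that("apply_performance_rules escalates critical errors only", {
  inv <- micro_scheme("S1", "cystic fibrosis", "sequencing")
  reqs <- derive_requirements(one_tech_center(), 2024, 297)

  crit <- new_history("C1", "S1", 2023L, "critical_interpretation_error", TRUE)
  out <- apply_performance_rules(reqs, crit, 2024, inv)
  esc <- out[out$reason == "S4-escalation", ]
  expect_equal(nrow(esc), 1)
  expect_equal(esc$subject, "cystic fibrosis")
  expect_equal(esc$due_year, 2024L)

  # clerical error with documented CAPA: no new requirement, no flag
  ok <- new_history("C1", "S1", 2023L, "clerical_error", TRUE)
  out <- apply_performance_rules(reqs, ok, 2024, inv)
  expect_equal(nrow(out), nrow(reqs))
  expect_equal(nrow(attr(out, "capa_flags")), 0)

  # clerical error without CAPA: flagged but frequency unchanged
  bad <- new_history("C1", "S1", 2023L, "clerical_error", FALSE)
  out <- apply_performance_rules(reqs, bad, 2024, inv)
  expect_equal(nrow(out), nrow(reqs))
  expect_equal(attr(out, "capa_flags")$scheme_id, "S1")

  # empty history is the identity
  out <- apply_performance_rules(reqs, new_history(), 2024, inv)
  expect_equal(nrow(out), nrow(reqs))
})

test_that("satisfies_requirement implements the matching semantics", {
  reqs <- derive_requirements(one_tech_center(technique = "karyotyping",
                                              indication = "constitutional karyotype"),
                              2024, 297)
  tech_req <- reqs[reqs$aspect == "technique_coverage", ][1, ]
  gi_req <- reqs[reqs$aspect == "genotyping_interpretation", ][1, ]

  # a virtual karyotype-image scheme counts for the technique
  virt <- micro_scheme("V1", "constitutional karyotype", "karyotyping",
                       flags = c(0, 0, 1), modality = "virtual")
  expect_true(satisfies_requirement(virt[1, ], tech_req))
  # and, being interpretation-only, also for genotyping/interpretation
  expect_true(satisfies_requirement(virt[1, ], gi_req))

  # a technique-only scheme does not discharge genotyping/interpretation
  tonly <- micro_scheme("T1", "constitutional karyotype", "karyotyping",
                        flags = c(1, 0, 0))
  expect_false(satisfies_requirement(tonly[1, ], gi_req))
  expect_true(satisfies_requirement(tonly[1, ], tech_req))

  # indication mismatch
  other <- micro_scheme("O1", "cystic fibrosis", "karyotyping")
  expect_false(satisfies_requirement(other[1, ], gi_req))

  # indications compare case-insensitively after whitespace normalization
  shouty <- micro_scheme("S9", "Constitutional  KARYOTYPE", "karyotyping")
  expect_true(satisfies_requirement(shouty[1, ], gi_req))
})

test_that("the planner prefers cheaper equivalent schemes every year", {
  inv <- rbind(micro_scheme("A", "cystic fibrosis", "sequencing",
                            fee_eur = 200),
               micro_scheme("B", "cystic fibrosis", "sequencing",
                            fee_eur = 100))
  class(inv) <- c("eqa_inventory", "data.frame")
  ctr <- one_tech_center("2023-06-01", 50L)  # annual technique
  p <- build_plan(ctr, inv, NULL, 2024:2026, 297)
  for (y in as.character(2024:2026)) {
    expect_equal(p$assignments[[y]], "B")
  }
})

test_that("equivalent same-fee schemes rotate deterministically", {
  inv <- rbind(micro_scheme("A", "cystic fibrosis", "sequencing"),
               micro_scheme("B", "cystic fibrosis", "sequencing"))
  class(inv) <- c("eqa_inventory", "data.frame")
  ctr <- one_tech_center("2023-06-01", 50L)
  p1 <- build_plan(ctr, inv, NULL, 2024:2026, 297)
  expect_equal(unname(vapply(as.character(2024:2026),
                             function(y) p1$assignments[[y]], "")),
               c("A", "B", "A"))
  # byte-identical determinism
  p2 <- build_plan(ctr, inv, NULL, 2024:2026, 297)
  expect_identical(p1, p2)
})

test_that("a triennial obligation covered in history waits until Y+3", {
  inv <- micro_scheme("A", "cystic fibrosis", "sequencing")
  ctr <- one_tech_center("2015-01-01", 400L)  # technique exempt (triennial)
  hist <- new_history("C1", "A", 2023L, "satisfactory", TRUE)
  p <- build_plan(ctr, inv, hist, 2024:2026, 297)
  expect_equal(p$assignments[["2024"]], character(0))
  expect_equal(p$assignments[["2025"]], character(0))
  expect_equal(p$assignments[["2026"]], "A")  # window ending 2023+3
})

test_that("infeasible requirements are reported by subject", {
  # no scheme covers genotyping/interpretation for the indication
  inv <- micro_scheme("T1", "cystic fibrosis", "sequencing",
                      flags = c(1, 0, 0))
  ctr <- one_tech_center("2023-06-01", 50L)
  expect_error(build_plan(ctr, inv, NULL, 2024:2026, 297),
               "infeasible.*cystic fibrosis")
})

test_that("greedy plans cost at least as much as exhaustive plans", {
  for (s in c(11, 12, 13)) {
    inst <- make_instance(s)
    pe <- build_plan(inst$ctr, inst$inv, inst$hist, inst$horizon, 297,
                     optimizer = "exhaustive")
    pg <- build_plan(inst$ctr, inst$inv, inst$hist, inst$horizon, 297,
                     optimizer = "greedy")
    expect_gte(plan_fee(pg, inst$inv), plan_fee(pe, inst$inv))
    expect_false(any_overdue(audit_compliance(inst$ctr, inst$inv, inst$hist,
                                              pg, inst$horizon, 297),
                             include_due = TRUE))
  }
})

test_that("escalations force a covering assignment the following year", {
  inv <- rbind(micro_scheme("A", "cystic fibrosis", "sequencing",
                            fee_eur = 500),
               micro_scheme("B", "spinal muscular atrophy", "mlpa",
                            fee_eur = 500))
  class(inv) <- c("eqa_inventory", "data.frame")
  tech <- data.frame(technique_id = c("sequencing", "mlpa"),
                     validation_date = as.Date(c("2010-01-01", "2010-01-01")),
                     method_class = "in_house",
                     annual_volume = c(1000L, 1000L),
                     last_method_change = as.Date(c(NA, NA)),
                     exemption_documented = TRUE)
  ind <- data.frame(indication = c("cystic fibrosis",
                                   "spinal muscular atrophy"),
                    annual_requests = 10L)
  ind$techniques_used <- list("sequencing", "mlpa")
  ctr <- micro_center(tech, ind)
  hist <- new_history(rep("C1", 2), c("A", "B"), rep(2023L, 2),
                      c("genotyping_error", "satisfactory"), c(TRUE, TRUE))
  p <- build_plan(ctr, inv, hist, 2024:2026, 297)
  expect_true("A" %in% p$assignments[["2024"]])
  expect_true("S4-escalation" %in% p$justifications[["2024"]][["A"]])
  # the unaffected indication, covered in 2023, can wait until 2026
  expect_false("B" %in% p$assignments[["2024"]])
})

test_that("review_triggers revokes exemptions on change events", {
  inv <- micro_scheme("A", "cystic fibrosis", "sequencing")
  ctr <- one_tech_center("2015-01-01", 400L)
  p <- build_plan(ctr, inv, NULL, 2024:2026, 297)
  expect_equal(p$exemptions$technique_id, "sequencing")

  ev <- data.frame(type = "method_change", technique_id = "sequencing",
                   stringsAsFactors = FALSE)
  fl <- review_triggers(ev, p, ctr, 297)
  expect_equal(fl$flag, "exemption_revoked")

  ev <- data.frame(type = "volume_change", technique_id = "sequencing",
                   new_volume = 100L, stringsAsFactors = FALSE)
  fl <- review_triggers(ev, p, ctr, 297)
  expect_equal(fl$flag, "exemption_revoked")

  # a sub-threshold volume wiggle does not trigger anything
  ev$new_volume <- 380L
  expect_equal(nrow(review_triggers(ev, p, ctr, 297)), 0)

  ev <- data.frame(type = "new_scheme", scheme_id = "Z9",
                   stringsAsFactors = FALSE)
  expect_equal(review_triggers(ev, p, ctr, 297)$flag, "reoptimize_optional")

  expect_equal(nrow(review_triggers(NULL, p, ctr, 297)), 0)
})
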