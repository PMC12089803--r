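test_that("GAD-7 scoring applies the >=10 threshold and validates items", {
  expect_equal(score_gad7(rep(0, 7)), data.frame(score = 0, case = FALSE))
  expect_equal(score_gad7(c(2, 1, 2, 1, 2, 1, 1)),
               data.frame(score = 10, case = TRUE))
  expect_equal(score_gad7(rep(3, 7)), data.frame(score = 21, case = TRUE))
  expect_true(is.na(score_gad7(c(1, NA, 1, 1, 1, 1, 1))$score))
  expect_error(score_gad7(c(4, 0, 0, 0, 0, 0, 0)), "0..3")
  expect_error(score_gad7(rep(1, 6)), "7 items")
})

test_that("CIDI-SF scoring gates on the cardinal symptom and criteria", {
  full <- data.frame(id = "a", mdd_cardinal_mood = 1,
                     mdd_cardinal_anhedonia = 0, mdd_symptom_count = 6,
                     mdd_duration_2wk = 1, mdd_impairment = 1,
                     gad_excessive_worry = 1, gad_duration_6mo = 1,
                     gad_symptom_count = 4)
  expect_true(score_cidi_sf(full)$mdd)
  expect_true(score_cidi_sf(full)$gad)
  no_cardinal <- transform(full, mdd_cardinal_mood = 0)
  expect_false(score_cidi_sf(no_cardinal)$mdd)
  few <- transform(full, mdd_symptom_count = 4)
  expect_false(score_cidi_sf(few)$mdd)
  # a missing required item yields a missing flag, never control
  na_item <- transform(full, mdd_duration_2wk = NA)
  expect_true(is.na(score_cidi_sf(na_item)$mdd))
  expect_error(score_cidi_sf(full[, -2]), "missing columns")
  # thresholds are configurable
  expect_true(score_cidi_sf(few, cidi_config(mdd_min_symptoms = 3))$mdd)
})

test_that("medication rule counts antidepressants and non-temazepam benzodiazepines", {
  rec <- make_records(3)
  rec$interview <- data.frame(
    id = c("p01", "p02", "p03"),
    code = c("BZ_TEMAZEPAM", "BZ_DIAZEPAM", "AD_SERTRALINE"),
    kind = "medication", stringsAsFactors = FALSE)
  anx <- classify_definition(rec, "medication_self_report", "anxiety")
  expect_equal(anx$status, c("control", "case", "case"))
  mood <- classify_definition(rec, "medication_self_report", "mood")
  expect_equal(mood$status, c("control", "control", "case"))
})

test_that("help-seeking counts either the GP or the psychiatrist question", {
  rec <- make_records(3)
  rec$touchscreen$psych_help <- c(1L, 0L, 0L)
  rec$touchscreen$gp_help <- c(0L, 1L, 0L)
  for (dis in c("mood", "anxiety", "internalising")) {
    st <- classify_definition(rec, "help_seeking", dis)
    expect_equal(st$status, c("case", "case", "control"))
  }
})

test_that("source availability drives missing status", {
  rec <- make_records(2, mhq = c(FALSE, TRUE))
  st <- classify_definition(rec, "cidi_sf", "mood")
  expect_equal(st$status, c("missing", "control"))
  st <- classify_definition(rec, "mhq_self_report", "anxiety")
  expect_equal(st$status, c("missing", "control"))
  rec2 <- make_records(2, primary_care = c(FALSE, TRUE))
  st <- classify_definition(rec2, "primary_care", "mood")
  expect_equal(st$status, c("missing", "control"))
  expect_error(classify_definition(rec, "gp_records", "mood"), "unknown")
  expect_error(classify_definition(rec, "cidi_sf", "psychosis"), "unknown")
})

test_that("internalising combination is a union with symmetric missingness", {
  expect_equal(combine_internalising("case", "missing"), "case")
  expect_equal(combine_internalising("control", "control"), "control")
  expect_equal(combine_internalising("missing", "missing"), "missing")
  expect_equal(combine_internalising("control", "missing"), "missing")
  expect_equal(combine_internalising(c("case", "control"),
                                     c("case", "case")),
               c("case", "case"))
})

test_that("exclusions union EHR, interview and MHQ routes", {
  rec <- make_records(4)
  expect_identical(apply_exclusions(rec), character())
  rec$ehr <- data.frame(id = "p01", code = "EU31", source = "primary_care",
                        stringsAsFactors = FALSE)
  rec$mhq_diagnosis <- data.frame(id = "p03", label = "schizophrenia",
                                  stringsAsFactors = FALSE)
  rec$interview <- data.frame(id = "p04", code = "SR_BIPOLAR",
                              kind = "diagnosis", stringsAsFactors = FALSE)
  expect_setequal(apply_exclusions(rec), c("p01", "p03", "p04"))
  flags <- derive_definitions(rec)
  expect_false(any(flags$id %in% c("p01", "p03", "p04")))
  expect_setequal(attr(flags, "excluded"), c("p01", "p03", "p04"))
})

test_that("code matching normalises and supports prefixes", {
  expect_true(match_codes("f32.0", "F320"))
  expect_false(match_codes("F321", "F320"))
  expect_true(match_codes("F3201", "F320", prefix = TRUE))
})

test_that("prevalence removes missing and survives degenerate tables", {
  flags <- data.frame(
    id = sprintf("i%03d", 1:105),
    definition = "hospital", disorder = "mood",
    status = c(rep("case", 10), rep("control", 90), rep("missing", 5)),
    stringsAsFactors = FALSE)
  rep1 <- prevalence_report(flags)
  expect_equal(rep1$prevalence, 0.10)
  expect_equal(rep1$n_missing, 5)
  all_missing <- transform(flags, status = "missing")
  rep2 <- prevalence_report(all_missing)
  expect_true(is.na(rep2$prevalence))
  expect_equal(completion_pct(1950, 7454), 26.16)
  expect_error(completion_pct(10, 0), "invalid")
})

test_that("derived flags satisfy the union and help-seeking invariants", {
  cfg <- sim_config(n_individuals = 2500, n_variants = 60, seed = 29)
  co <- simulate_cohort(cfg)
  flags <- derive_definitions(co$records, co$code_lists)
  for (def in definition_names()) {
    n_int <- sum(status_of(flags, def, "internalising") == "case")
    n_mood <- sum(status_of(flags, def, "mood") == "case")
    n_anx <- sum(status_of(flags, def, "anxiety") == "case")
    expect_gte(n_int, max(n_mood, n_anx))
  }
  hs <- lapply(c("mood", "anxiety", "internalising"),
               function(d) status_of(flags, "help_seeking", d))
  expect_identical(hs[[1]], hs[[2]])
  expect_identical(hs[[1]], hs[[3]])
})
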