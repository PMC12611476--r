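test_that("severity grade map covers the qualifying codes with the stated grades", {
  expect_equal(as.character(severity_of_code(c("F32.0", "F33.9", "F34.1", "F38.1"))),
               rep("leicht", 4))
  expect_equal(as.character(severity_of_code(c("F32.1", "F33.1"))), rep("mittel", 2))
  expect_equal(as.character(severity_of_code(c("F32.2", "F33.2"))), rep("schwer", 2))
  expect_equal(as.character(severity_of_code(c("F32.3", "F33.3"))),
               rep("sehr_schwer", 2))
  expect_equal(as.character(severity_of_code("F33.4")), "unassigned")
  expect_true(is.na(severity_of_code("F20.0")))
  # strict ordering for worst-diagnosis comparisons
  expect_true(severity_of_code("F32.3") > severity_of_code("F32.2"))
  expect_true(severity_of_code("F32.2") > severity_of_code("F32.1"))
  expect_true(severity_of_code("F32.1") > severity_of_code("F32.0"))
  expect_true(severity_of_code("F32.0") > severity_of_code("F33.4"))
})

test_that("index assignment follows the three-rule hierarchy", {
  # rule 1: worst diagnosis within the case becomes the index diagnosis
  cases <- fx_case("a", "p", 2016, 1)
  dx <- dplyr::bind_rows(fx_dx("a", "F32.1"), fx_dx("a", "F32.2"))
  got <- assign_index_and_severity(cases, dx)
  expect_equal(got$index_diagnosis, "F32.2")
  expect_equal(as.character(got$severity), "schwer")

  # rule 2: among same-day cases, ambulatory beats inpatient
  cases <- dplyr::bind_rows(
    fx_case("amb", "p", 2016, 1, setting = "ambulatory"),
    fx_case("inp", "p", 2016, 1, setting = "inpatient")
  )
  dx <- dplyr::bind_rows(fx_dx("amb", "F32.0"), fx_dx("inp", "F32.2"))
  got <- assign_index_and_severity(cases, dx)
  expect_equal(got$index_case_id, "amb")
  expect_equal(got$index_diagnosis, "F32.0")
  expect_equal(as.character(got$severity), "leicht")

  # rule 3: among same-day ambulatory cases, priority specialty groups win
  cases <- dplyr::bind_rows(
    fx_case("gp", "p", 2016, 1, specialty_group = "01"),
    fx_case("pt", "p", 2016, 1, specialty_group = "51")
  )
  dx <- dplyr::bind_rows(fx_dx("gp", "F32.2"), fx_dx("pt", "F33.1"))
  got <- assign_index_and_severity(cases, dx)
  expect_equal(got$index_case_id, "pt")
  expect_equal(got$index_diagnosis, "F33.1")
  expect_equal(as.character(got$severity), "mittel")
  expect_true(got$tie_break)

  # earliest case start wins before any tie-break applies
  cases <- dplyr::bind_rows(
    fx_case("late", "p", 2016, 1, start_offset = 20L, specialty_group = "51"),
    fx_case("early", "p", 2016, 1, start_offset = 2L, specialty_group = "01")
  )
  dx <- dplyr::bind_rows(fx_dx("late", "F32.3"), fx_dx("early", "F32.0"))
  expect_equal(assign_index_and_severity(cases, dx)$index_case_id, "early")
})

test_that("index assignment is invariant under input row order", {
  cases <- dplyr::bind_rows(
    fx_case("b2", "p", 2016, 1, specialty_group = "21"),
    fx_case("a1", "p", 2016, 1, specialty_group = "27")
  )
  dx <- dplyr::bind_rows(fx_dx("b2", "F32.1"), fx_dx("a1", "F32.1"))
  fwd <- assign_index_and_severity(cases, dx)
  rev <- assign_index_and_severity(cases[2:1, ], dx[2:1, ])
  expect_equal(fwd, rev)
  expect_equal(fwd$index_case_id, "a1")  # documented lexicographic tie-break
})

test_that("cohort selection applies criteria and logs first failure in fixed order", {
  persons <- dplyr::bind_rows(
    fx_person("ok"), fx_person("washout"), fx_person("young", birth_year = 2000L),
    fx_person("noconf"), fx_person("noindex"),
    fx_person("short", enrolled_from = as.Date("2015-06-01"))
  )
  cases <- dplyr::bind_rows(
    fx_case("ok_i", "ok", 2016, 1), fx_case("ok_c", "ok", 2016, 3),
    fx_case("w_i", "washout", 2016, 1), fx_case("w_c", "washout", 2016, 2),
    fx_case("w_prior", "washout", 2015, 4),
    fx_case("y_i", "young", 2016, 1), fx_case("y_c", "young", 2016, 2),
    fx_case("n_i", "noconf", 2016, 1),
    fx_case("x_other", "noindex", 2016, 2),
    fx_case("s_i", "short", 2016, 1), fx_case("s_c", "short", 2016, 2)
  )
  diagnoses <- dplyr::bind_rows(
    fx_dx("ok_i", "F32.1"), fx_dx("ok_c", "F33.1"),
    fx_dx("w_i", "F32.1"), fx_dx("w_c", "F32.1"), fx_dx("w_prior", "F32.9"),
    fx_dx("y_i", "F32.1"), fx_dx("y_c", "F32.1"),
    fx_dx("n_i", "F32.1"),
    fx_dx("x_other", "F32.1"),
    fx_dx("s_i", "F32.1"), fx_dx("s_c", "F32.1")
  )
  b <- claims_bundle(persons, cases, diagnoses,
                     fx_service("ok", "2016-02-01", "PROB50")[0, ], "pre")
  sel <- select_cohort(b, "2016Q1")
  expect_equal(sel$cohort$person_id, "ok")
  got <- tibble::deframe(sel$exclusions)
  expect_equal(got[["washout"]], "prior_diagnosis")
  expect_equal(got[["young"]], "age")
  expect_equal(got[["noconf"]], "no_confirmation")
  expect_equal(got[["noindex"]], "no_index_diagnosis")
  expect_equal(got[["short"]], "enrollment")

  # washout beats age when both fail (fixed precedence)
  expect_equal(got[["washout"]], "prior_diagnosis")

  m <- sel$cohort
  expect_equal(m$index_case_id, "ok_i")
  expect_equal(as.character(m$severity), "mittel")
  expect_equal(m$window_end, m$window_start + 365L)
  expect_equal(m$age_at_index, 2016L - 1976L)
  expect_equal(m$diagnosis_site, "ambulatory_hausarzt")
  expect_true(m$alcohol == FALSE && m$drugs == FALSE && m$psychoses == FALSE)
})

test_that("qualifier must match the care sector", {
  # a 'gesichert' diagnosis on an inpatient case does not qualify
  persons <- fx_person("p")
  cases <- dplyr::bind_rows(
    fx_case("i", "p", 2016, 1, setting = "inpatient", specialty_group = "00"),
    fx_case("c", "p", 2016, 2)
  )
  dx <- dplyr::bind_rows(fx_dx("i", "F32.2", "gesichert"), fx_dx("c", "F32.1"))
  b <- claims_bundle(persons, cases, dx, fx_service("p", "2016-02-01", "PROB50")[0, ], "pre")
  sel <- suppressWarnings(select_cohort(b, "2016Q1"))
  expect_equal(nrow(sel$cohort), 0L)
  expect_equal(sel$exclusions$reason, "no_index_diagnosis")

  # the same code as a primary discharge diagnosis does qualify
  dx2 <- dplyr::bind_rows(fx_dx("i", "F32.2", "hauptentlassung"), fx_dx("c", "F32.1"))
  b2 <- claims_bundle(persons, cases, dx2, b$services, "pre")
  sel2 <- select_cohort(b2, "2016Q1")
  expect_equal(sel2$cohort$person_id, "p")
  expect_equal(sel2$cohort$diagnosis_site, "hospital")
})

test_that("comorbidity flags respond to prefix hits inside the window", {
  persons <- fx_person("p")
  cases <- dplyr::bind_rows(
    fx_case("i", "p", 2016, 1),
    fx_case("c", "p", 2016, 3)
  )
  dx <- dplyr::bind_rows(
    fx_dx("i", "F32.1"), fx_dx("c", "F33.1"),
    fx_dx("c", "F10.2"), fx_dx("c", "F20.0")
  )
  b <- claims_bundle(persons, cases, dx,
                     fx_service("p", "2016-02-01", "PROB50")[0, ], "pre")
  m <- select_cohort(b, "2016Q1")$cohort
  expect_true(m$alcohol)
  expect_false(m$drugs)
  expect_true(m$psychoses)
})

test_that("selection on synthetic data matches generator ground truth exactly", {
  cfg <- scenario_config("pre", n_persons = 4000, seed = 42)
  b <- generate_bundle(cfg)
  gt <- ground_truth(cfg, b)
  sel <- select_cohort(b, c(cfg$index_year, cfg$index_quarter))
  joined <- gt %>%
    dplyr::left_join(sel$exclusions, by = "person_id") %>%
    dplyr::mutate(reason = dplyr::coalesce(reason, "none"))
  expect_identical(joined$reason, joined$exclusion_reason)
  # recovered severity equals planted severity for every included member
  sev <- dplyr::inner_join(sel$cohort, gt, by = "person_id")
  expect_identical(as.character(sev$severity.x), sev$severity.y)
  # every member passes the independent criteria re-checker
  expect_true(all(check_cohort(sel$cohort, b, c(cfg$index_year, cfg$index_quarter))))
})
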