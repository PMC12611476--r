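test_that("generation is deterministic given the seed", {
  cfg <- scenario_config("pre", n_persons = 100, seed = 7)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  for (tbl in c("persons", "cases", "diagnoses", "services")) {
    expect_identical(b1[[tbl]], b2[[tbl]])
  }
  expect_identical(attr(b1, "ground_truth"), attr(b2, "ground_truth"))
  b3 <- generate_bundle(scenario_config("pre", n_persons = 100, seed = 8))
  expect_false(identical(b1$services, b3$services))
})

test_that("config invariants are enforced", {
  expect_error(scenario_config("pre", severity_mix = c(leicht = 0.5, mittel = 0.4,
                                                       schwer = 0.2,
                                                       sehr_schwer = 0, unassigned = 0)),
               "summing to 1")
  expect_error(scenario_config("pre", n_persons = 0), "n_persons")
  expect_error(scenario_config("pre",
                               pathway_mix = c("2.3" = 0.5, no_pt_service = 0.5)),
               "catalogue")
  expect_warning(generate_bundle(scenario_config("pre", n_persons = 20, seed = 1,
                                                 contamination = c(prior_diagnosis = 1,
                                                                   no_confirmation = 0,
                                                                   age = 0))),
                 "contaminated")
})

test_that("a degenerate pathway mix produces exactly that service sequence", {
  cfg <- scenario_config("pre", n_persons = 150, seed = 11,
                         pathway_mix = c("1.1" = 1),
                         contamination = c(prior_diagnosis = 0,
                                           no_confirmation = 0, age = 0))
  b <- generate_bundle(cfg)
  sel <- select_cohort(b, c(2016, 1))
  expect_equal(nrow(sel$exclusions), 0L)
  seg <- compress_to_segments(truncate_gaps(map_services(sel$cohort, b)))
  keys <- seg %>%
    dplyr::group_by(person_id) %>%
    dplyr::summarise(key = paste(category, collapse = ">"))
  expect_equal(nrow(keys), 150L)
  expect_true(all(keys$key == "probatorik>kzt"))
})

test_that("ground truth bookkeeping matches the drawn assignment", {
  cfg <- scenario_config("post", n_persons = 1000, seed = 3)
  b <- generate_bundle(cfg)
  gt <- ground_truth(cfg, b)
  expect_equal(nrow(gt), 1000L)
  expect_setequal(unique(gt$exclusion_reason),
                  c("none", "prior_diagnosis", "no_confirmation", "age"))
  # contamination-free persons carry a pathway; contaminated carry none
  expect_true(all(!is.na(gt$pathway[gt$exclusion_reason == "none"])))
  expect_true(all(is.na(gt$pathway[gt$exclusion_reason != "none"])))
  # a mismatched config is refused
  expect_error(ground_truth(scenario_config("post", n_persons = 1000, seed = 4), b),
               "does not match")
  # persons planted with a washout violation really have one
  index_qi <- quarter_index(cfg$index_year, cfg$index_quarter)
  prior <- gt$person_id[gt$exclusion_reason == "prior_diagnosis"]
  prior_cases <- b$cases %>%
    dplyr::filter(person_id %in% prior) %>%
    dplyr::mutate(qi = quarter_index(quarter_year, quarter)) %>%
    dplyr::group_by(person_id) %>%
    dplyr::summarise(has_washout_case = any(qi >= index_qi - 4L & qi < index_qi))
  expect_true(all(prior_cases$has_washout_case))
})

test_that("planted severity mix is recovered within three binomial SEs", {
  cfg <- scenario_config("pre", n_persons = 30000, seed = 9)
  b <- generate_bundle(cfg)
  gt <- ground_truth(cfg, b)
  shares <- prop.table(table(factor(gt$severity, names(cfg$severity_mix))))
  for (g in names(cfg$severity_mix)) {
    p <- cfg$severity_mix[[g]]
    se <- sqrt(p * (1 - p) / nrow(gt))
    expect_lt(abs(shares[[g]] - p), 3 * se + 1e-12)
  }
})

test_that("generated services respect the window and the gap rule", {
  cfg <- scenario_config("post", n_persons = 2000, seed = 13)
  b <- generate_bundle(cfg)
  sel <- select_cohort(b, c(2018, 1))
  ev <- map_services(sel$cohort, b)
  # nothing outside the 365-day window was generated for cohort members
  trunc <- truncate_gaps(ev)
  expect_equal(nrow(attr(trunc, "truncation_log")), 0L)
  expect_equal(nrow(trunc), nrow(ev))
})
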