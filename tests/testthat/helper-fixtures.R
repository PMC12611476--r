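# In-code fixtures shared across the suite. Everything is built
# programmatically; no files on disk.

fx_origin <- as.Date("2016-01-04")

fx_person <- function(person_id, birth_year = 1976L, sex = "female",
                      urbanicity = "stadt",
                      enrolled_from = as.Date("2014-01-01"),
                      enrolled_to = as.Date("2018-01-01")) {
  tibble::tibble(person_id = person_id, birth_year = as.integer(birth_year),
                 sex = sex, urbanicity = urbanicity,
                 enrolled_from = enrolled_from, enrolled_to = enrolled_to)
}

fx_case <- function(case_id, person_id, year, quarter, start_offset = 3L,
                    length_days = 10L, setting = "ambulatory",
                    specialty_group = "01") {
  start <- quarter_start(year, quarter) + start_offset
  tibble::tibble(case_id = case_id, person_id = person_id,
                 quarter_year = as.integer(year), quarter = as.integer(quarter),
                 start_date = start, end_date = start + length_days,
                 setting = setting, specialty_group = specialty_group)
}

fx_dx <- function(case_id, icd_code, qualifier = "gesichert") {
  tibble::tibble(case_id = case_id, icd_code = icd_code, qualifier = qualifier)
}

fx_service <- function(person_id, date, ebm_code, unit_count = 1L,
                       provider_specialty_group = "51") {
  tibble::tibble(person_id = person_id, service_date = as.Date(date),
                 ebm_code = ebm_code, unit_count = as.integer(unit_count),
                 provider_specialty_group = provider_specialty_group)
}

# Two persons, three cases, four diagnoses, five services; person p1 is a
# textbook cohort member (index Q1-2016, confirmation Q3-2016).
fx_tiny_bundle <- function() {
  persons <- dplyr::bind_rows(fx_person("p1"), fx_person("p2"))
  cases <- dplyr::bind_rows(
    fx_case("c1", "p1", 2016, 1),
    fx_case("c2", "p1", 2016, 3),
    fx_case("c3", "p2", 2016, 1)
  )
  diagnoses <- dplyr::bind_rows(
    fx_dx("c1", "F32.1"),
    fx_dx("c1", "F10.2"),
    fx_dx("c2", "F33.1"),
    fx_dx("c3", "F32.9")
  )
  services <- dplyr::bind_rows(
    fx_service("p1", "2016-01-20", "PROB50"),
    fx_service("p1", "2016-02-03", "PROB50"),
    fx_service("p1", "2016-03-30", "KZT50"),
    fx_service("p1", "2016-04-13", "KZT50"),
    fx_service("p2", "2016-02-01", "SPR25", unit_count = 2L)
  )
  claims_bundle(persons, cases, diagnoses, services, "pre")
}

# Event-table builder for service/pathway/interval tests: days are
# offsets from fx_origin.
fx_events <- function(person_id, day, category, sessions = 1) {
  tibble::tibble(
    person_id = person_id,
    date = fx_origin + day,
    category = factor(category, levels = service_categories),
    sessions = sessions
  ) %>%
    dplyr::arrange(person_id, date, category)
}

fx_cohort_row <- function(person_id, severity = "mittel",
                          window_start = fx_origin) {
  tibble::tibble(person_id = person_id,
                 severity = factor(severity, levels = severity_levels,
                                   ordered = TRUE),
                 window_start = window_start,
                 window_end = window_start + 365L)
}

# Event rows without bookkeeping attributes, for identity comparisons.
fx_strip_log <- function(events) {
  attr(events, "truncation_log") <- NULL
  as.data.frame(events)
}

# Independent brute-force pathway matcher: collapse the date-ordered
# merged-category sequence to runs, refuse revisits, then compare
# literally against every catalogue definition.
fx_brute_match <- function(categories_in_date_order, catalogue) {
  merged <- merge_therapy_arm(as.character(categories_in_date_order))
  runs <- rle(merged)$values
  if (anyDuplicated(runs) > 0L) return("unmatched")
  hit <- which(vapply(catalogue$segments, identical, logical(1L), y = runs))
  if (length(hit) == 1L) catalogue$pathway_id[[hit]] else "unmatched"
}

# Independent Mann-Whitney oracle: full enumeration over all C(n, nx)
# group labellings of the pooled values.
fx_u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

fx_mwu_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_obs <- fx_u_stat(x, y)
  us <- apply(utils::combn(length(pooled), nx), 2, function(ix) {
    fx_u_stat(pooled[ix], pooled[-ix])
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
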