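#' Depression severity grades
#'
#' Severity of a depression diagnosis is read off the ICD-10-GM code:
#' mild (`leicht`): F32.0, F32.8, F32.9, F33.0, F33.8, F33.9, F34.1,
#' F38.1; moderate (`mittel`): F32.1, F33.1; severe (`schwer`): F32.2,
#' F33.2; very severe (`sehr_schwer`): F32.3, F33.3; no grade assignable
#' (`unassigned`): F33.4 (recurrent disorder currently in remission) and
#' any other qualifying code without a listed grade. For "worst
#' diagnosis" comparisons the grades are strictly ordered
#' `sehr_schwer > schwer > mittel > leicht > unassigned`.
#'
#' @format `severity_levels` is a character vector of the five grades in
#'   increasing order of severity.
#' @export
severity_levels <- c("unassigned", "leicht", "mittel", "schwer", "sehr_schwer")

severity_code_map <- c(
  "F32.0" = "leicht", "F32.8" = "leicht", "F32.9" = "leicht",
  "F33.0" = "leicht", "F33.8" = "leicht", "F33.9" = "leicht",
  "F34.1" = "leicht", "F38.1" = "leicht",
  "F32.1" = "mittel", "F33.1" = "mittel",
  "F32.2" = "schwer", "F33.2" = "schwer",
  "F32.3" = "sehr_schwer", "F33.3" = "sehr_schwer",
  "F33.4" = "unassigned"
)

#' @rdname severity_levels
#' @param icd_code Character vector of ICD-10-GM codes.
#' @return `severity_of_code()` returns an ordered factor over
#'   `severity_levels`; non-qualifying codes map to `NA`.
#' @export
severity_of_code <- function(icd_code) {
  grade <- unname(severity_code_map[icd_code])
  grade[is.na(grade) & is_qualifying_code(icd_code)] <- "unassigned"
  factor(grade, levels = severity_levels, ordered = TRUE)
}

#' @rdname severity_levels
#' @return `is_qualifying_code()` returns a logical vector: `TRUE` for
#'   any F32.x / F33.x code plus F34.1 and F38.1.
#' @export
is_qualifying_code <- function(icd_code) {
  grepl("^F3[23](\\.|$)", icd_code) | icd_code %in% c("F34.1", "F38.1")
}

#' Cohort selection rule set
#'
#' Bundles the configurable pieces of cohort selection: which diagnosis
#' qualifiers count in which care setting, the washout length, the
#' provider specialty groups prioritised in the severity hierarchy (and
#' used to classify the diagnosis site as psychotherapist-adjacent), the
#' general-practice specialty groups, the comorbidity code prefixes and
#' whether continuous enrollment over washout plus observation window is
#' required.
#'
#' @param washout_quarters Number of full calendar quarters before the
#'   index quarter that must be free of qualifying diagnoses (default 4,
#'   i.e. a 12-month diagnosis-free lead-in).
#' @param priority_specialty_groups Two-digit specialty-group codes of
#'   medical and psychological psychotherapists, neurologists and
#'   psychiatrists, prioritised when concurrent cases carry depression
#'   diagnoses.
#' @param hausarzt_groups Two-digit specialty-group codes treated as
#'   general practice when classifying the diagnosis site.
#' @param comorbidity_prefixes Named list of ICD prefix vectors for the
#'   three mental-comorbidity flags.
#' @param require_enrollment Require enrollment to cover washout start
#'   through window end.
#' @return A list of class `selection_ruleset`.
#' @export
selection_ruleset <- function(washout_quarters = 4L,
                              priority_specialty_groups = c("51", "53", "58", "59", "60", "61", "68"),
                              hausarzt_groups = c("01", "02", "03"),
                              comorbidity_prefixes = list(
                                alcohol = "F10",
                                drugs = c("F11", "F12", "F13", "F14", "F15", "F16", "F18", "F19"),
                                psychoses = c("F20", "F22", "F23", "F24", "F25", "F28", "F29")
                              ),
                              require_enrollment = TRUE) {
  stopifnot(washout_quarters >= 1L,
            all(c("alcohol", "drugs", "psychoses") %in% names(comorbidity_prefixes)))
  structure(
    list(
      washout_quarters = as.integer(washout_quarters),
      priority_specialty_groups = priority_specialty_groups,
      hausarzt_groups = hausarzt_groups,
      comorbidity_prefixes = comorbidity_prefixes,
      require_enrollment = isTRUE(require_enrollment)
    ),
    class = "selection_ruleset"
  )
}

# A diagnosis qualifies when the code is a depression code and the
# qualifier matches the sector: "gesichert" (confirmed) in ambulatory
# care, "hauptentlassung" (primary discharge) in inpatient care.
qualifying_diagnoses <- function(bundle) {
  bundle$diagnoses %>%
    dplyr::inner_join(bundle$cases, by = "case_id") %>%
    dplyr::filter(
      is_qualifying_code(.data$icd_code),
      (.data$qualifier == "gesichert" & .data$setting == "ambulatory") |
        (.data$qualifier == "hauptentlassung" & .data$setting == "inpatient")
    ) %>%
    dplyr::mutate(case_qi = quarter_index(.data$quarter_year, .data$quarter))
}

#' Choose index case and index diagnosis by the severity hierarchy
#'
#' Applies the hierarchical assignment to one person's index-quarter
#' cases that carry qualifying depression diagnoses: candidate cases are
#' those with the earliest start date; among concurrent candidates,
#' ambulatory cases beat inpatient ones, then priority specialty groups
#' beat other specialties, and a remaining tie is broken by the
#' lexicographically smallest `case_id` (reported in the `tie_break`
#' column). Within the chosen case the worst-grade diagnosis becomes the
#' index diagnosis.
#'
#' @param cases Tibble of one person's index-quarter cases.
#' @param diagnoses Tibble of qualifying diagnoses of those cases
#'   (columns `case_id`, `icd_code`; qualifier-setting matching is
#'   assumed done).
#' @param ruleset A [selection_ruleset()].
#' @return One-row tibble: `index_case_id`, `index_diagnosis`,
#'   `severity`, `window_start`, `tie_break`.
#' @export
assign_index_and_severity <- function(cases, diagnoses, ruleset = selection_ruleset()) {
  cand <- cases %>%
    dplyr::semi_join(diagnoses, by = "case_id") %>%
    dplyr::filter(.data$start_date == min(.data$start_date)) %>%
    dplyr::arrange(.data$setting != "ambulatory",
                   !(.data$specialty_group %in% ruleset$priority_specialty_groups),
                   .data$case_id)
  if (nrow(cand) == 0L) {
    stop("no index-quarter case with a qualifying diagnosis", call. = FALSE)
  }
  chosen <- cand[1L, ]
  dx <- diagnoses %>%
    dplyr::filter(.data$case_id == chosen$case_id) %>%
    dplyr::mutate(severity = severity_of_code(.data$icd_code)) %>%
    dplyr::arrange(dplyr::desc(.data$severity), .data$icd_code)
  tibble::tibble(
    index_case_id = chosen$case_id,
    index_diagnosis = dx$icd_code[[1L]],
    severity = dx$severity[[1L]],
    window_start = chosen$start_date,
    tie_break = nrow(cand) > 1L
  )
}

#' Classify where the index diagnosis was made
#'
#' Inpatient (or hospital-ambulatory) cases map to `hospital`; ambulatory
#' cases map to `ambulatory_hausarzt`, `ambulatory_psychotherapeut`
#' (priority specialty groups: medical/psychological psychotherapists,
#' neurologists, psychiatrists) or `ambulatory_other` by specialty group.
#'
#' @param setting,specialty_group Vectors from the index case.
#' @param ruleset A [selection_ruleset()].
#' @return Character vector of site labels.
#' @export
classify_diagnosis_site <- function(setting, specialty_group,
                                    ruleset = selection_ruleset()) {
  dplyr::case_when(
    setting == "inpatient" ~ "hospital",
    specialty_group %in% ruleset$hausarzt_groups ~ "ambulatory_hausarzt",
    specialty_group %in% ruleset$priority_specialty_groups ~ "ambulatory_psychotherapeut",
    TRUE ~ "ambulatory_other"
  )
}

#' Flag mental comorbidities over the observation window
#'
#' A flag is set when any confirmed/primary-discharge diagnosis whose
#' code starts with one of the flag's configured prefixes occurs in a
#' case overlapping the member's `[window_start, window_end)` window.
#'
#' @param members Tibble with `person_id`, `window_start`, `window_end`.
#' @param bundle A `claims_bundle`.
#' @param ruleset A [selection_ruleset()].
#' @return `members` with logical columns `alcohol`, `drugs`, `psychoses`.
#' @export
flag_comorbidities <- function(members, bundle, ruleset = selection_ruleset()) {
  dx <- bundle$diagnoses %>%
    dplyr::inner_join(bundle$cases, by = "case_id") %>%
    dplyr::filter(.data$qualifier %in% c("gesichert", "hauptentlassung")) %>%
    dplyr::inner_join(dplyr::select(members, "person_id", "window_start", "window_end"),
                      by = "person_id") %>%
    dplyr::filter(.data$start_date < .data$window_end,
                  .data$end_date >= .data$window_start)
  prefix_hit <- function(codes, prefixes) {
    Reduce(`|`, lapply(prefixes, function(p) startsWith(codes, p)),
           init = rep(FALSE, length(codes)))
  }
  flags <- dx %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::summarise(
      alcohol = any(prefix_hit(.data$icd_code, ruleset$comorbidity_prefixes$alcohol)),
      drugs = any(prefix_hit(.data$icd_code, ruleset$comorbidity_prefixes$drugs)),
      psychoses = any(prefix_hit(.data$icd_code, ruleset$comorbidity_prefixes$psychoses)),
      .groups = "drop"
    )
  members %>%
    dplyr::left_join(flags, by = "person_id") %>%
    dplyr::mutate(dplyr::across(c("alcohol", "drugs", "psychoses"),
                                ~ dplyr::coalesce(.x, FALSE)))
}

#' Select the incident-depression cohort
#'
#' Applies the inclusion criteria to a claims bundle: (b) a qualifying
#' depression diagnosis (code plus sector-matched qualifier) in a case of
#' the index quarter; (c) no qualifying diagnosis in any case of the
#' `washout_quarters` calendar quarters before the index quarter; (a) age
#' 21--90 at window start (age = index year minus birth year); (d) a
#' qualifying diagnosis in a case of a different calendar quarter whose
#' start date lies within the 365-day window from the first day of the
#' index case; (e) enrollment covering washout start through window end
#' (if required by the ruleset). Excluded persons are logged with the
#' first failed criterion in the fixed order (b), (c), (a), (d), (e).
#'
#' @param bundle A `claims_bundle`.
#' @param index_quarter The index quarter, e.g. `"2016Q1"` or `c(2016, 1)`.
#' @param ruleset A [selection_ruleset()].
#' @return A list with `cohort` (one row per included member: index case,
#'   index diagnosis, severity, observation window, age, diagnosis site,
#'   comorbidity flags) and `exclusions` (`person_id`, `reason`).
#' @export
select_cohort <- function(bundle, index_quarter, ruleset = selection_ruleset()) {
  validate_bundle(bundle)
  iq <- parse_quarter(index_quarter)
  index_qi <- quarter_index(iq$year, iq$quarter)
  qdx <- qualifying_diagnoses(bundle)

  if (!any(qdx$case_qi == index_qi)) {
    warning("index quarter ", iq$year, "Q", iq$quarter,
            " carries no qualifying diagnosis; empty cohort", call. = FALSE)
  }

  persons <- bundle$persons
  has_index <- unique(qdx$person_id[qdx$case_qi == index_qi])
  washout_lo <- index_qi - ruleset$washout_quarters
  has_prior <- unique(qdx$person_id[qdx$case_qi >= washout_lo & qdx$case_qi < index_qi])

  # Index case + severity for everyone passing (b): vectorised version of
  # assign_index_and_severity() across persons.
  idx_dx <- qdx %>% dplyr::filter(.data$case_qi == index_qi)
  cand <- idx_dx %>%
    dplyr::distinct(.data$person_id, .data$case_id, .data$start_date,
                    .data$setting, .data$specialty_group) %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::filter(.data$start_date == min(.data$start_date)) %>%
    dplyr::arrange(.data$setting != "ambulatory",
                   !(.data$specialty_group %in% ruleset$priority_specialty_groups),
                   .data$case_id, .by_group = TRUE) %>%
    dplyr::mutate(tie_break = dplyr::n() > 1L) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup()
  index_dx <- idx_dx %>%
    dplyr::semi_join(cand, by = c("person_id", "case_id")) %>%
    dplyr::mutate(severity = severity_of_code(.data$icd_code)) %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::arrange(dplyr::desc(.data$severity), .data$icd_code, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::select("person_id", index_diagnosis = "icd_code", "severity")

  members <- cand %>%
    dplyr::select("person_id", index_case_id = "case_id",
                  window_start = "start_date", index_setting = "setting",
                  index_specialty_group = "specialty_group", "tie_break") %>%
    dplyr::left_join(index_dx, by = "person_id") %>%
    dplyr::mutate(window_end = .data$window_start + 365L) %>%
    dplyr::left_join(dplyr::select(persons, "person_id", "birth_year", "sex",
                                   "urbanicity", "enrolled_from", "enrolled_to"),
                     by = "person_id") %>%
    dplyr::mutate(age_at_index = iq$year - .data$birth_year)

  # Confirmation: qualifying diagnosis in a case of a different quarter
  # whose start lies inside the member's window.
  confirm <- qdx %>%
    dplyr::filter(.data$case_qi != index_qi) %>%
    dplyr::inner_join(dplyr::select(members, "person_id", "window_start", "window_end"),
                      by = "person_id") %>%
    dplyr::filter(.data$start_date >= .data$window_start,
                  .data$start_date < .data$window_end)
  has_confirm <- unique(confirm$person_id)

  washout_start <- quarter_start(index_quarter_year(washout_lo),
                                 index_quarter_number(washout_lo))
  members <- members %>%
    dplyr::mutate(
      fail_index = FALSE,
      fail_prior = .data$person_id %in% has_prior,
      fail_age = .data$age_at_index < 21L | .data$age_at_index > 90L,
      fail_confirm = !(.data$person_id %in% has_confirm),
      fail_enroll = ruleset$require_enrollment &
        !(.data$enrolled_from <= washout_start & .data$enrolled_to >= .data$window_end)
    )

  no_index <- persons %>%
    dplyr::filter(!(.data$person_id %in% has_index)) %>%
    dplyr::transmute(.data$person_id, reason = "no_index_diagnosis")

  reason <- with(members, dplyr::case_when(
    fail_prior ~ "prior_diagnosis",
    fail_age ~ "age",
    fail_confirm ~ "no_confirmation",
    fail_enroll ~ "enrollment",
    TRUE ~ NA_character_
  ))
  exclusions <- dplyr::bind_rows(
    no_index,
    tibble::tibble(person_id = members$person_id, reason = reason) %>%
      dplyr::filter(!is.na(.data$reason))
  ) %>% dplyr::arrange(.data$person_id)

  cohort <- members %>%
    dplyr::filter(is.na(reason)) %>%
    dplyr::mutate(
      diagnosis_site = classify_diagnosis_site(.data$index_setting,
                                               .data$index_specialty_group, ruleset)
    ) %>%
    dplyr::select("person_id", "index_case_id", "index_diagnosis", "severity",
                  "window_start", "window_end", "age_at_index", "sex",
                  "urbanicity", "diagnosis_site", "tie_break") %>%
    flag_comorbidities(bundle, ruleset)

  list(cohort = cohort, exclusions = exclusions)
}

#' Independent re-check of the inclusion criteria
#'
#' Re-tests every returned cohort member against the raw tables with a
#' straightforward per-person loop, independent of the vectorised
#' selection path. Intended for validation and tests.
#'
#' @inheritParams select_cohort
#' @param cohort The `cohort` tibble returned by [select_cohort()].
#' @return Logical vector, one element per cohort row; `TRUE` when all
#'   criteria re-verify.
#' @export
check_cohort <- function(cohort, bundle, index_quarter,
                         ruleset = selection_ruleset()) {
  iq <- parse_quarter(index_quarter)
  index_qi <- quarter_index(iq$year, iq$quarter)
  qdx <- qualifying_diagnoses(bundle)
  washout_lo <- index_qi - ruleset$washout_quarters
  washout_start <- quarter_start(index_quarter_year(washout_lo),
                                 index_quarter_number(washout_lo))
  vapply(seq_len(nrow(cohort)), function(i) {
    m <- cohort[i, ]
    p <- bundle$persons[bundle$persons$person_id == m$person_id, ]
    d <- qdx[qdx$person_id == m$person_id, ]
    ok_b <- any(d$case_qi == index_qi)
    ok_c <- !any(d$case_qi >= washout_lo & d$case_qi < index_qi)
    ok_a <- m$age_at_index >= 21L && m$age_at_index <= 90L
    ok_d <- any(d$case_qi != index_qi &
                  d$start_date >= m$window_start & d$start_date < m$window_end)
    ok_e <- !ruleset$require_enrollment ||
      (p$enrolled_from <= washout_start && p$enrolled_to >= m$window_end)
    idx <- d[d$case_id == m$index_case_id, ]
    ok_sev <- nrow(idx) > 0L &&
      identical(as.character(max(severity_of_code(idx$icd_code))),
                as.character(m$severity))
    ok_b && ok_c && ok_a && ok_d && ok_e && ok_sev
  }, logical(1L))
}
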