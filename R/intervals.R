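#' First-contact to first-therapy intervals
#'
#' For each cohort member with both a first contact (consultation or
#' probatory session) and at least one therapy service (guideline
#' therapy or acute treatment) whose first therapy is not before the
#' contact, computes the gap in days between the two, the type of the
#' first therapy service (`richtlinie` or `akut`), and, where present,
#' the separate gaps to the first guideline-therapy and first
#' acute-treatment service. Members whose only therapy precedes their
#' first contact are excluded from the interval population and counted,
#' as are therapy-only and contact-only members; the counts are attached
#' as attribute `excluded` (named integer vector).
#'
#' @param cohort Cohort tibble from [select_cohort()].
#' @param events Gap-truncated service events, see [truncate_gaps()].
#' @return Tibble with one row per member in the interval population:
#'   `person_id`, `severity`, `contact_date`, `therapy_date`,
#'   `therapy_type`, `gap_days`, `gap_richtlinie_days`, `gap_akut_days`.
#' @export
compute_intervals <- function(cohort, events) {
  contacts <- first_contact(events)
  ther <- first_therapy(events, "therapie")
  richt <- first_therapy(events, "richtlinie") %>%
    dplyr::select("person_id", richtlinie_date = "therapy_date")
  akut <- first_therapy(events, "akut") %>%
    dplyr::select("person_id", akut_date = "therapy_date")

  joined <- contacts %>%
    dplyr::full_join(ther, by = "person_id") %>%
    dplyr::left_join(richt, by = "person_id") %>%
    dplyr::left_join(akut, by = "person_id")

  excluded <- c(
    contact_only = sum(!is.na(joined$contact_date) & is.na(joined$therapy_date)),
    therapy_only = sum(is.na(joined$contact_date) & !is.na(joined$therapy_date)),
    therapy_before_contact = sum(!is.na(joined$contact_date) &
                                   !is.na(joined$therapy_date) &
                                   joined$therapy_date < joined$contact_date)
  )

  records <- joined %>%
    dplyr::filter(!is.na(.data$contact_date), !is.na(.data$therapy_date),
                  .data$therapy_date >= .data$contact_date) %>%
    dplyr::mutate(
      therapy_type = dplyr::if_else(.data$therapy_category == "akut",
                                    "akut", "richtlinie"),
      gap_days = as.numeric(.data$therapy_date - .data$contact_date),
      gap_richtlinie_days = dplyr::if_else(
        !is.na(.data$richtlinie_date) & .data$richtlinie_date >= .data$contact_date,
        as.numeric(.data$richtlinie_date - .data$contact_date), NA_real_),
      gap_akut_days = dplyr::if_else(
        !is.na(.data$akut_date) & .data$akut_date >= .data$contact_date,
        as.numeric(.data$akut_date - .data$contact_date), NA_real_)
    ) %>%
    dplyr::inner_join(dplyr::select(cohort, "person_id", "severity"),
                      by = "person_id") %>%
    dplyr::select("person_id", "severity", "contact_date", "therapy_date",
                  "therapy_type", "gap_days", "gap_richtlinie_days",
                  "gap_akut_days")
  attr(records, "excluded") <- excluded
  records
}

#' Summarise interval gaps, optionally stratified
#'
#' Computes n, mean, SD (n-1 denominator), median (even n: mean of the
#' two central values), minimum and maximum of the contact-to-therapy
#' gap, overall or stratified by severity or by therapy type. For the
#' therapy-type strata the gap to the first service *of that type* is
#' used (`gap_richtlinie_days` / `gap_akut_days`), mirroring how the
#' per-type rows of a time-to-therapy table are populated.
#'
#' @param records Interval records from [compute_intervals()].
#' @param strata `"none"`, `"severity"` or `"therapy_type"`.
#' @return Tibble with columns `stratum`, `n`, `mean`, `sd`, `median`,
#'   `min`, `max`.
#' @export
interval_summary <- function(records, strata = c("none", "severity", "therapy_type")) {
  strata <- match.arg(strata)
  summarise_gaps <- function(df, label) {
    x <- df$.gap
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      return(tibble::tibble(stratum = label, n = 0L, mean = NA_real_,
                            sd = NA_real_, median = NA_real_,
                            min = NA_real_, max = NA_real_))
    }
    tibble::tibble(stratum = label, n = length(x), mean = mean(x),
                   sd = stats::sd(x), median = stats::median(x),
                   min = min(x), max = max(x))
  }
  if (strata == "none") {
    summarise_gaps(dplyr::mutate(records, .gap = .data$gap_days), "all")
  } else if (strata == "severity") {
    records %>%
      dplyr::mutate(.gap = .data$gap_days,
                    severity = factor(.data$severity, levels = severity_levels)) %>%
      dplyr::group_by(.data$severity) %>%
      dplyr::group_map(~ summarise_gaps(.x, as.character(.y$severity))) %>%
      dplyr::bind_rows()
  } else {
    dplyr::bind_rows(
      summarise_gaps(dplyr::mutate(records, .gap = .data$gap_richtlinie_days),
                     "richtlinie"),
      summarise_gaps(dplyr::mutate(records, .gap = .data$gap_akut_days), "akut")
    )
  }
}
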