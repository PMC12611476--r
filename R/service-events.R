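#' Psychotherapeutic service categories
#'
#' The seven billing categories the pipeline recognises, in their
#' declared order (used for stable sorting and same-day tie-breaks):
#' consultation (`sprechstunde`), probatory sessions (`probatorik`),
#' acute treatment (`akut`), short-term therapy individual/group
#' (`kzt_einzel`, `kzt_gruppe`) and long-term therapy individual/group
#' (`lzt_einzel`, `lzt_gruppe`). Derived groupings: guideline therapy
#' (`richtlinie_categories()`), therapy services
#' (`therapie_categories()` = guideline therapy plus acute treatment) and
#' contact services (`contact_categories()` = consultation plus
#' probatory).
#'
#' @format `service_categories` is a character vector of the seven
#'   category names in declared order.
#' @export
service_categories <- c("sprechstunde", "probatorik", "akut",
                        "kzt_einzel", "kzt_gruppe", "lzt_einzel", "lzt_gruppe")

#' @rdname service_categories
#' @export
richtlinie_categories <- function() {
  c("kzt_einzel", "kzt_gruppe", "lzt_einzel", "lzt_gruppe")
}

#' @rdname service_categories
#' @export
therapie_categories <- function() c(richtlinie_categories(), "akut")

#' @rdname service_categories
#' @export
contact_categories <- function() c("sprechstunde", "probatorik")

#' @rdname service_categories
#' @param category Character vector of category names.
#' @return `merge_therapy_arm()` collapses the individual/group arms of
#'   short- and long-term therapy to `"kzt"` / `"lzt"` (used for pathway
#'   matching and the same-service gap rule).
#' @export
merge_therapy_arm <- function(category) {
  sub("_(einzel|gruppe)$", "", category)
}

#' Demonstration fee-schedule code map
#'
#' Maps symbolic fee-schedule codes to a service category and the billed
#' unit length in minutes. Consultation and acute treatment are billed
#' in 25-minute units, all other categories in 50-minute units. Real
#' analyses supply their own map via a CSV with the same three columns.
#'
#' @return Tibble with columns `ebm_code`, `category`, `unit_minutes`.
#' @export
default_code_map <- function() {
  tibble::tribble(
    ~ebm_code, ~category,     ~unit_minutes,
    "SPR25",   "sprechstunde", 25,
    "AKUT25",  "akut",         25,
    "PROB50",  "probatorik",   50,
    "KZT50",   "kzt_einzel",   50,
    "KZTG50",  "kzt_gruppe",   50,
    "LZT50",   "lzt_einzel",   50,
    "LZTG50",  "lzt_gruppe",   50
  )
}

validate_code_map <- function(code_map) {
  stopifnot(all(c("ebm_code", "category", "unit_minutes") %in% names(code_map)))
  if (!all(code_map$category %in% service_categories)) {
    stop("code map contains unknown categories: ",
         paste(setdiff(code_map$category, service_categories), collapse = ", "),
         call. = FALSE)
  }
  if (!all(code_map$unit_minutes %in% c(25, 50))) {
    stop("unit_minutes must be 25 or 50", call. = FALSE)
  }
  invisible(code_map)
}

#' Map raw service records to session-normalised service events
#'
#' Joins each member's billed services against the code map, keeps only
#' services dated inside the member's `[window_start, window_end)`
#' window, converts billed units to 50-minute session equivalents
#' (`sessions = unit_count * unit_minutes / 50`), merges same-day
#' same-category records by summing sessions, and sorts stably by
#' date and declared category order. Codes absent from the map are
#' ignored; their record count is attached as attribute
#' `n_unmapped_records`.
#'
#' @param cohort Cohort tibble from [select_cohort()] (needs
#'   `person_id`, `window_start`, `window_end`).
#' @param bundle A `claims_bundle`.
#' @param code_map A code map tibble, see [default_code_map()].
#' @return Tibble of service events: `person_id`, `date`, `category`,
#'   `sessions`, ordered by person, date, category.
#' @export
map_services <- function(cohort, bundle, code_map = default_code_map()) {
  validate_code_map(code_map)
  mapped <- bundle$services %>%
    dplyr::inner_join(dplyr::select(cohort, "person_id", "window_start", "window_end"),
                      by = "person_id")
  n_unmapped <- sum(!(mapped$ebm_code %in% code_map$ebm_code))
  events <- mapped %>%
    dplyr::inner_join(dplyr::select(code_map, "ebm_code", "category", "unit_minutes"),
                      by = "ebm_code") %>%
    dplyr::filter(.data$service_date >= .data$window_start,
                  .data$service_date < .data$window_end) %>%
    dplyr::mutate(
      category = factor(.data$category, levels = service_categories),
      sessions = .data$unit_count * .data$unit_minutes / 50
    ) %>%
    dplyr::group_by(.data$person_id, date = .data$service_date, .data$category) %>%
    dplyr::summarise(sessions = sum(.data$sessions), .groups = "drop") %>%
    dplyr::arrange(.data$person_id, .data$date, .data$category)
  attr(events, "n_unmapped_records") <- n_unmapped
  events
}

#' First contact with a psychotherapist
#'
#' The first contact is the earliest consultation (`sprechstunde`) or
#' probatory (`probatorik`) event in the observation window. A same-day
#' tie between the two resolves to the consultation (flagged in
#' `tie_break`).
#'
#' @param events Service-event tibble from [map_services()] (may cover
#'   many persons; grouped internally by `person_id`).
#' @return One row per person that has a contact event: `person_id`,
#'   `contact_date`, `contact_category`, `tie_break`.
#' @export
first_contact <- function(events) {
  events %>%
    dplyr::filter(.data$category %in% contact_categories()) %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::arrange(.data$date, .data$category, .by_group = TRUE) %>%
    dplyr::summarise(
      contact_date = .data$date[1L],
      contact_category = as.character(.data$category[1L]),
      tie_break = sum(.data$date == .data$date[1L]) > 1L,
      .groups = "drop"
    )
}

#' First therapy service
#'
#' Earliest event whose category lies in the requested subset: all
#' therapy services (`"therapie"` = guideline therapy plus acute
#' treatment), guideline therapy only (`"richtlinie"`), or acute
#' treatment only (`"akut"`).
#'
#' @param events Service-event tibble from [map_services()].
#' @param subset One of `"therapie"`, `"richtlinie"`, `"akut"`.
#' @return One row per person that has such an event: `person_id`,
#'   `therapy_date`, `therapy_category`.
#' @export
first_therapy <- function(events, subset = c("therapie", "richtlinie", "akut")) {
  subset <- match.arg(subset)
  cats <- switch(subset,
                 therapie = therapie_categories(),
                 richtlinie = richtlinie_categories(),
                 akut = "akut")
  events %>%
    dplyr::filter(.data$category %in% cats) %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::arrange(.data$date, .data$category, .by_group = TRUE) %>%
    dplyr::summarise(
      therapy_date = .data$date[1L],
      therapy_category = as.character(.data$category[1L]),
      .groups = "drop"
    )
}
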