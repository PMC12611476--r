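#' Claims bundle: the four linked claims tables for one period
#'
#' A `claims_bundle` carries the synthetic statutory-insurance claims
#' tables the pipeline consumes: insured persons, quarter-based treatment
#' cases, case-level diagnoses and person-level billed services, plus a
#' period label (`"pre"` or `"post"` reform). Construction validates the
#' schema and referential integrity; all downstream stages may assume a
#' valid bundle.
#'
#' Dates are calendar dates (class `Date`, no time component). All
#' intervals in this package are half-open `[start, end)` in whole days;
#' in particular `enrolled_to` and a case's `end_date` are stored as the
#' last covered day plus the half-open convention is applied where
#' windows are compared (see [select_cohort()]).
#'
#' @param persons Tibble with columns `person_id`, `birth_year`, `sex`
#'   (`"female"`/`"male"`), `urbanicity` (`"stadt"`/`"mischkreis"`/`"land"`),
#'   `enrolled_from`, `enrolled_to`.
#' @param cases Tibble with columns `case_id`, `person_id`, `quarter_year`,
#'   `quarter`, `start_date`, `end_date`, `setting`
#'   (`"ambulatory"`/`"inpatient"`), `specialty_group` (two-digit string).
#' @param diagnoses Tibble with columns `case_id`, `icd_code`, `qualifier`
#'   (`"gesichert"`/`"hauptentlassung"`/`"other"`).
#' @param services Tibble with columns `person_id`, `service_date`,
#'   `ebm_code`, `unit_count`, `provider_specialty_group`.
#' @param period_label `"pre"` or `"post"`.
#' @return An object of class `claims_bundle`: a named list of the four
#'   tibbles plus `period_label`.
#' @seealso [read_bundle()], [write_bundle()], [generate_bundle()]
#' @export
claims_bundle <- function(persons, cases, diagnoses, services,
                          period_label = c("pre", "post")) {
  period_label <- match.arg(period_label)
  bundle <- structure(
    list(
      persons = tibble::as_tibble(persons),
      cases = tibble::as_tibble(cases),
      diagnoses = tibble::as_tibble(diagnoses),
      services = tibble::as_tibble(services),
      period_label = period_label
    ),
    class = "claims_bundle"
  )
  validate_bundle(bundle)
  bundle
}

bundle_schema <- list(
  persons = c("person_id", "birth_year", "sex", "urbanicity",
              "enrolled_from", "enrolled_to"),
  cases = c("case_id", "person_id", "quarter_year", "quarter",
            "start_date", "end_date", "setting", "specialty_group"),
  diagnoses = c("case_id", "icd_code", "qualifier"),
  services = c("person_id", "service_date", "ebm_code", "unit_count",
               "provider_specialty_group")
)

#' Validate a claims bundle
#'
#' Checks the column schema, enum domains, per-table invariants
#' (enrollment order, case date order and quarter containment for
#' ambulatory cases, positive unit counts, ICD code shape) and
#' referential integrity across the four tables. Called by
#' [claims_bundle()], [read_bundle()] and [write_bundle()].
#'
#' @param bundle A `claims_bundle`.
#' @return Invisibly `TRUE`; aborts with an informative error otherwise.
#' @export
validate_bundle <- function(bundle) {
  if (!inherits(bundle, "claims_bundle")) {
    stop("not a claims_bundle", call. = FALSE)
  }
  for (tbl in names(bundle_schema)) {
    missing_cols <- setdiff(bundle_schema[[tbl]], names(bundle[[tbl]]))
    if (length(missing_cols) > 0L) {
      stop(sprintf("table '%s' is missing column(s): %s",
                   tbl, paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
  }
  p <- bundle$persons
  cs <- bundle$cases
  dg <- bundle$diagnoses
  sv <- bundle$services

  stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

  stop_if(anyDuplicated(p$person_id) > 0L, "duplicate person_id in persons")
  stop_if(anyDuplicated(cs$case_id) > 0L, "duplicate case_id in cases")
  stop_if(!all(p$sex %in% c("female", "male")), "persons$sex outside {female, male}")
  stop_if(!all(p$urbanicity %in% c("stadt", "mischkreis", "land")),
          "persons$urbanicity outside {stadt, mischkreis, land}")
  stop_if(!all(p$birth_year >= 1900L & p$birth_year <= 2010L),
          "persons$birth_year outside plausible range 1900-2010")
  stop_if(!all(p$enrolled_from <= p$enrolled_to),
          "persons with enrolled_from > enrolled_to")
  stop_if(!all(cs$setting %in% c("ambulatory", "inpatient")),
          "cases$setting outside {ambulatory, inpatient}")
  stop_if(!all(cs$start_date <= cs$end_date), "cases with start_date > end_date")
  amb <- cs$setting == "ambulatory"
  if (any(amb)) {
    qs <- quarter_start(cs$quarter_year[amb], cs$quarter[amb])
    qe <- quarter_end_exclusive(cs$quarter_year[amb], cs$quarter[amb])
    stop_if(!all(cs$start_date[amb] >= qs & cs$end_date[amb] < qe),
            "ambulatory case dates outside their calendar quarter")
  }
  stop_if(!all(dg$qualifier %in% c("gesichert", "hauptentlassung", "other")),
          "diagnoses$qualifier outside {gesichert, hauptentlassung, other}")
  stop_if(!all(grepl("^[A-Z][0-9]{2}(\\.[0-9]+)?$", dg$icd_code)),
          "diagnoses$icd_code not of the form letter + digits [+ .suffix]")
  stop_if(!all(sv$unit_count >= 1L), "services$unit_count below 1")

  dangling_case_person <- setdiff(cs$person_id, p$person_id)
  if (length(dangling_case_person) > 0L) {
    stop("integrity error: cases reference unknown person_id(s): ",
         paste(utils::head(dangling_case_person, 5L), collapse = ", "),
         call. = FALSE)
  }
  dangling_diag_case <- setdiff(dg$case_id, cs$case_id)
  if (length(dangling_diag_case) > 0L) {
    stop("integrity error: diagnoses reference unknown case_id(s): ",
         paste(utils::head(dangling_diag_case, 5L), collapse = ", "),
         call. = FALSE)
  }
  dangling_service_person <- setdiff(sv$person_id, p$person_id)
  if (length(dangling_service_person) > 0L) {
    stop("integrity error: services reference unknown person_id(s): ",
         paste(utils::head(dangling_service_person, 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat(sprintf("<claims_bundle: period '%s'>\n", x$period_label))
  cat(sprintf("  persons:   %d\n", nrow(x$persons)))
  cat(sprintf("  cases:     %d\n", nrow(x$cases)))
  cat(sprintf("  diagnoses: %d\n", nrow(x$diagnoses)))
  cat(sprintf("  services:  %d\n", nrow(x$services)))
  invisible(x)
}

bundle_col_types <- list(
  persons = readr::cols(
    person_id = readr::col_character(),
    birth_year = readr::col_integer(),
    sex = readr::col_character(),
    urbanicity = readr::col_character(),
    enrolled_from = readr::col_date(format = "%Y-%m-%d"),
    enrolled_to = readr::col_date(format = "%Y-%m-%d")
  ),
  cases = readr::cols(
    case_id = readr::col_character(),
    person_id = readr::col_character(),
    quarter_year = readr::col_integer(),
    quarter = readr::col_integer(),
    start_date = readr::col_date(format = "%Y-%m-%d"),
    end_date = readr::col_date(format = "%Y-%m-%d"),
    setting = readr::col_character(),
    specialty_group = readr::col_character()
  ),
  diagnoses = readr::cols(
    case_id = readr::col_character(),
    icd_code = readr::col_character(),
    qualifier = readr::col_character()
  ),
  services = readr::cols(
    person_id = readr::col_character(),
    service_date = readr::col_date(format = "%Y-%m-%d"),
    ebm_code = readr::col_character(),
    unit_count = readr::col_integer(),
    provider_specialty_group = readr::col_character()
  )
)

#' Read a claims bundle from a directory of CSV tables
#'
#' Expects `persons.csv`, `cases.csv`, `diagnoses.csv` and `services.csv`
#' (comma-separated, UTF-8, header row, ISO-8601 dates) in
#' `directory_path`. The returned bundle has passed full validation,
#' including referential integrity.
#'
#' @param directory_path Directory containing the four CSV files.
#' @param period_label `"pre"` or `"post"`.
#' @return A `claims_bundle`.
#' @export
read_bundle <- function(directory_path, period_label = c("pre", "post")) {
  period_label <- match.arg(period_label)
  tables <- lapply(names(bundle_schema), function(tbl) {
    path <- file.path(directory_path, paste0(tbl, ".csv"))
    if (!file.exists(path)) {
      stop(sprintf("load error: table '%s' not found at %s", tbl, path),
           call. = FALSE)
    }
    out <- readr::read_csv(path, col_types = bundle_col_types[[tbl]],
                           progress = FALSE, locale = readr::locale(encoding = "UTF-8"))
    missing_cols <- setdiff(bundle_schema[[tbl]], names(out))
    if (length(missing_cols) > 0L) {
      stop(sprintf("load error: table '%s' is missing column(s): %s",
                   tbl, paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    out
  })
  names(tables) <- names(bundle_schema)
  claims_bundle(tables$persons, tables$cases, tables$diagnoses,
                tables$services, period_label)
}

#' Write a claims bundle to a directory of CSV tables
#'
#' Inverse of [read_bundle()]: writes the four tables as UTF-8 CSV with
#' ISO-8601 dates so that `read_bundle(write_bundle(b))` reproduces `b`
#' field for field. A bundle that fails validation is refused.
#'
#' @param bundle A valid `claims_bundle`.
#' @param directory_path Target directory (created if absent).
#' @return Invisibly, `directory_path`.
#' @export
write_bundle <- function(bundle, directory_path) {
  validate_bundle(bundle)
  if (!dir.exists(directory_path)) {
    dir.create(directory_path, recursive = TRUE)
  }
  for (tbl in names(bundle_schema)) {
    out <- dplyr::select(bundle[[tbl]], dplyr::all_of(bundle_schema[[tbl]]))
    readr::write_csv(out, file.path(directory_path, paste0(tbl, ".csv")),
                     progress = FALSE)
  }
  invisible(directory_path)
}
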