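#' Scenario configuration for the synthetic claims generator
#'
#' Describes one simulated period: cohort size, index quarter, planted
#' severity and pathway mixes, the planted mean first-contact to
#' first-therapy gap, per-category session-count means, waiting-time
#' parameters and contamination rates (fractions of persons built to
#' violate exactly one inclusion criterion). Defaults reproduce the
#' study conditions of the respective period: index quarter Q1 2016
#' (pre) / Q1 2018 (post), the observed severity mix, the published
#' per-pathway shares among members with at least one psychotherapeutic
#' service, the share without any such service (82.5% pre / 77.2%
#' post), and overall mean contact-to-therapy gaps of 72.5 days (pre)
#' and 89.4 days (post).
#'
#' Probability vectors are checked to sum to 1 within 1e-9. The
#' `pathway_mix` is expressed over the full cohort and includes the
#' pseudo-pathways `"unmatched"` (a sequence outside the period's
#' catalogue) and `"no_pt_service"`.
#'
#' @param period `"pre"` or `"post"`.
#' @param n_persons Number of persons to simulate.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param index_year,index_quarter Index quarter (defaults by period).
#' @param severity_mix Named probabilities over the five severity grades.
#' @param pathway_mix Named full-cohort probabilities over the period's
#'   pathway ids plus `"unmatched"` and `"no_pt_service"`.
#' @param mean_contact_therapy_gap Planted expected gap in days between
#'   first contact and first therapy service for therapy pathways.
#' @param session_count_means Named mean session counts per merged
#'   category (`sprechstunde`, `probatorik`, `akut`, `kzt`, `lzt`).
#' @param within_gap_mean Mean days between consecutive sittings of the
#'   same stage.
#' @param default_transition_gap_mean Mean days for stage transitions
#'   other than the final transition into therapy.
#' @param gap_shape Gamma shape for all waiting-time draws (shape < 3
#'   gives the right-skewed, median-below-mean gaps seen in claims).
#' @param first_service_delay_mean Mean days from window start to the
#'   first psychotherapeutic service.
#' @param contamination Named rates: `prior_diagnosis` (qualifying
#'   diagnosis planted in the washout), `no_confirmation` (no
#'   second-quarter diagnosis), `age` (outside 21--90).
#' @param comorbidity_rates Named planted prevalences for the alcohol /
#'   drugs / psychoses flags.
#' @param sex_female,urbanicity_mix,age_mean,age_sd,site_mix Demographic
#'   mix parameters (defaults by period from the study populations).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(period = c("pre", "post"),
                            n_persons = 1000L,
                            seed = 1L,
                            index_year = NULL,
                            index_quarter = 1L,
                            severity_mix = NULL,
                            pathway_mix = NULL,
                            mean_contact_therapy_gap = NULL,
                            session_count_means = c(sprechstunde = 1.5,
                                                    probatorik = 2.5,
                                                    akut = 4, kzt = 10, lzt = 12),
                            within_gap_mean = 10,
                            default_transition_gap_mean = 14,
                            gap_shape = 2.8,
                            first_service_delay_mean = 20,
                            contamination = c(prior_diagnosis = 0.10,
                                              no_confirmation = 0.10,
                                              age = 0.05),
                            comorbidity_rates = NULL,
                            sex_female = NULL,
                            urbanicity_mix = NULL,
                            age_mean = NULL,
                            age_sd = 17.4,
                            site_mix = NULL) {
  period <- match.arg(period)
  pre <- period == "pre"
  if (is.null(index_year)) index_year <- if (pre) 2016L else 2018L
  if (is.null(severity_mix)) {
    severity_mix <- if (pre) {
      c(leicht = 0.656, mittel = 0.252, schwer = 0.075,
        sehr_schwer = 0.010, unassigned = 0.007)
    } else {
      # printed shares sum to 100.1%; renormalised to an exact simplex
      p <- c(leicht = 0.611, mittel = 0.295, schwer = 0.079,
             sehr_schwer = 0.010, unassigned = 0.006)
      p / sum(p)
    }
  }
  if (is.null(pathway_mix)) {
    pathway_mix <- if (pre) {
      c("1.1" = 0.462, "1.2" = 0.047, "1.3" = 0.338,
        unmatched = 0.153) * 0.175
    } else {
      c("2.1" = 0.371, "2.2" = 0.012, "2.3" = 0.063, "2.4" = 0.083,
        "2.5" = 0.292, unmatched = 0.179) * 0.228
    }
    pathway_mix <- c(pathway_mix, no_pt_service = 1 - sum(pathway_mix))
  }
  if (is.null(mean_contact_therapy_gap)) {
    mean_contact_therapy_gap <- if (pre) 72.5 else 89.4
  }
  if (is.null(comorbidity_rates)) {
    comorbidity_rates <- if (pre) {
      c(alcohol = 0.059, drugs = 0.037, psychoses = 0.038)
    } else {
      c(alcohol = 0.058, drugs = 0.040, psychoses = 0.036)
    }
  }
  if (is.null(sex_female)) sex_female <- if (pre) 0.653 else 0.636
  if (is.null(urbanicity_mix)) {
    urbanicity_mix <- if (pre) {
      c(stadt = 0.404, mischkreis = 0.339, land = 0.257)
    } else {
      c(stadt = 0.396, mischkreis = 0.343, land = 0.261)
    }
  }
  if (is.null(age_mean)) age_mean <- if (pre) 54.1 else 53.2
  if (is.null(site_mix)) {
    amb <- if (pre) c(0.688, 0.178, 0.134) else c(0.680, 0.194, 0.126)
    site_mix <- c(hospital = 0.028,
                  hausarzt = 0.972 * amb[[1L]],
                  psychotherapeut = 0.972 * amb[[2L]],
                  other = 0.972 * amb[[3L]])
    site_mix <- site_mix / sum(site_mix)
  }

  check_prob <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be a probability vector summing to 1", call. = FALSE)
    }
  }
  check_prob(severity_mix, "severity_mix")
  check_prob(pathway_mix, "pathway_mix")
  check_prob(urbanicity_mix, "urbanicity_mix")
  check_prob(site_mix, "site_mix")
  stopifnot(n_persons >= 1L,
            all(contamination >= 0 & contamination <= 1),
            sum(contamination) <= 1,
            all(comorbidity_rates >= 0 & comorbidity_rates <= 1),
            sex_female >= 0, sex_female <= 1,
            mean_contact_therapy_gap > 0, within_gap_mean > 0, gap_shape > 0)
  expected_ids <- c(pathway_catalogue(period)$pathway_id, "unmatched", "no_pt_service")
  if (!all(names(pathway_mix) %in% expected_ids)) {
    stop("pathway_mix names outside the '", period, "' catalogue: ",
         paste(setdiff(names(pathway_mix), expected_ids), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(period = period, n_persons = as.integer(n_persons),
         seed = as.integer(seed), index_year = as.integer(index_year),
         index_quarter = as.integer(index_quarter),
         severity_mix = severity_mix, pathway_mix = pathway_mix,
         mean_contact_therapy_gap = mean_contact_therapy_gap,
         session_count_means = session_count_means,
         within_gap_mean = within_gap_mean,
         default_transition_gap_mean = default_transition_gap_mean,
         gap_shape = gap_shape,
         first_service_delay_mean = first_service_delay_mean,
         contamination = contamination,
         comorbidity_rates = comorbidity_rates,
         sex_female = sex_female, urbanicity_mix = urbanicity_mix,
         age_mean = age_mean, age_sd = age_sd, site_mix = site_mix),
    class = "scenario_config"
  )
}

codes_by_grade <- list(
  leicht = c("F32.0", "F32.8", "F32.9", "F33.0", "F33.8", "F33.9",
             "F34.1", "F38.1"),
  mittel = c("F32.1", "F33.1"),
  schwer = c("F32.2", "F33.2"),
  sehr_schwer = c("F32.3", "F33.3"),
  unassigned = "F33.4"
)

category_code <- c(sprechstunde = "SPR25", akut = "AKUT25",
                   probatorik = "PROB50")

pathway_variant_segments <- function(pathway_id, period, variant_draw) {
  if (pathway_id == "unmatched") {
    return(if (period == "pre") "kzt" else "probatorik")
  }
  defs <- pathway_catalogue(period)
  rows <- which(defs$pathway_id == pathway_id)
  if (length(rows) == 1L) {
    defs$segments[[rows]]
  } else {
    defs$segments[[rows[1L + (variant_draw > 0.5)]]]
  }
}

rgamma_days <- function(n, mean, shape, lo = 1, hi = Inf) {
  if (n == 0L) return(numeric(0))
  pmin(pmax(round(stats::rgamma(n, shape = shape, scale = mean / shape)), lo), hi)
}

# Per-pathway mean for the final transition into the first therapy
# stage, chosen so that the expected contact-to-therapy gap equals the
# configured target.
final_edge_mean <- function(segments, config) {
  therapy <- c("kzt", "lzt", "akut")
  first_th <- which(segments %in% therapy)[1L]
  if (is.na(first_th)) return(NA_real_)
  contact <- segments[seq_len(first_th - 1L)]
  within_expected <- sum((config$session_count_means[contact] - 1) *
                           config$within_gap_mean)
  n_edges <- length(contact)
  max(1, config$mean_contact_therapy_gap - within_expected -
        (n_edges - 1L) * config$default_transition_gap_mean)
}

#' Generate a synthetic claims bundle
#'
#' Draws a full four-table claims bundle from a [scenario_config()]:
#' demographics, an index case with a qualifying depression diagnosis in
#' the index quarter (severity per the configured mix), a confirmation
#' diagnosis in a later calendar quarter inside the 365-day window,
#' planted comorbidity diagnoses, and a service sequence realising the
#' person's assigned pathway with gamma-distributed (right-skewed)
#' waiting times. Contaminated persons violate exactly their assigned
#' criterion. Same-type service runs never exceed the 91-day gap rule,
#' and all services fall inside the observation window, so generator
#' ground truth is exactly recoverable by the pipeline. Consultation and
#' acute-treatment sittings are billed as two 25-minute units, all other
#' categories as one 50-minute unit, so one sitting is one 50-minute
#' session equivalent throughout.
#'
#' The per-person intent is attached as attribute `ground_truth` (also
#' retrievable via [ground_truth()]): `person_id`, `exclusion_reason`
#' (`none`, `prior_diagnosis`, `no_confirmation`, `age`), `severity` and
#' `pathway` (a pathway id, `"unmatched"`, `"no_pt_service"`, or `NA`
#' for contaminated persons, which are generated without services).
#'
#' @param config A [scenario_config()].
#' @return A `claims_bundle` with attributes `ground_truth` and
#'   `scenario`.
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_persons
  person_id <- sprintf("P%06d", seq_len(n))
  iq_start <- quarter_start(config$index_year, config$index_quarter)
  iq_end <- quarter_end_exclusive(config$index_year, config$index_quarter)
  index_qi <- quarter_index(config$index_year, config$index_quarter)

  contam <- config$contamination
  reason <- sample(c("none", names(contam)), n, replace = TRUE,
                   prob = c(1 - sum(contam), contam))
  if (!any(reason == "none")) {
    warning("degenerate config: every simulated person is contaminated",
            call. = FALSE)
  }
  grade <- sample(names(config$severity_mix), n, replace = TRUE,
                  prob = config$severity_mix)
  index_code <- vapply(grade, function(g) {
    cs <- codes_by_grade[[g]]
    cs[[sample.int(length(cs), 1L)]]
  }, character(1L))
  pathway <- rep(NA_character_, n)
  incl <- reason == "none"
  pathway[incl] <- sample(names(config$pathway_mix), sum(incl), replace = TRUE,
                          prob = config$pathway_mix)

  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)), 21L), 90L)
  age[reason == "age"] <- sample(c(18:20, 91:95), sum(reason == "age"),
                                 replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(config$sex_female, 1 - config$sex_female))
  urbanicity <- sample(names(config$urbanicity_mix), n, replace = TRUE,
                       prob = config$urbanicity_mix)
  site <- sample(names(config$site_mix), n, replace = TRUE,
                 prob = config$site_mix)

  specialty <- dplyr::case_when(
    site == "hospital" ~ "00",
    site == "hausarzt" ~ sample(c("01", "02", "03"), n, replace = TRUE),
    site == "psychotherapeut" ~ sample(c("51", "53", "58", "59", "60", "61", "68"),
                                       n, replace = TRUE),
    TRUE ~ sample(c("10", "21", "27"), n, replace = TRUE)
  )

  washout_lo <- index_qi - 4L
  washout_start <- quarter_start(index_quarter_year(washout_lo),
                                 index_quarter_number(washout_lo))
  persons <- tibble::tibble(
    person_id = person_id,
    birth_year = config$index_year - age,
    sex = sex,
    urbanicity = urbanicity,
    enrolled_from = washout_start - 30L,
    enrolled_to = iq_start + 14L + 365L + 30L
  )

  # index case (window starts on its first day)
  index_start <- iq_start + sample(0:13, n, replace = TRUE)
  index_end <- pmin(index_start + sample(3:20, n, replace = TRUE), iq_end - 1L)
  cases <- tibble::tibble(
    case_id = paste0("C_idx_", person_id),
    person_id = person_id,
    quarter_year = config$index_year,
    quarter = config$index_quarter,
    start_date = index_start,
    end_date = index_end,
    setting = ifelse(site == "hospital", "inpatient", "ambulatory"),
    specialty_group = specialty
  )
  diagnoses <- tibble::tibble(
    case_id = cases$case_id,
    icd_code = index_code,
    qualifier = ifelse(site == "hospital", "hauptentlassung", "gesichert")
  )

  make_quarter_case <- function(ids, qi_offsets, suffix) {
    qi <- index_qi + qi_offsets
    y <- index_quarter_year(qi)
    q <- index_quarter_number(qi)
    qs <- quarter_start(y, q)
    qe <- quarter_end_exclusive(y, q)
    start <- qs + sample(0:40, length(ids), replace = TRUE)
    tibble::tibble(
      case_id = paste0("C_", suffix, "_", ids),
      person_id = ids,
      quarter_year = y,
      quarter = q,
      start_date = start,
      end_date = pmin(start + sample(3:20, length(ids), replace = TRUE), qe - 1L),
      setting = "ambulatory",
      specialty_group = "01"
    )
  }

  prior_ids <- person_id[reason == "prior_diagnosis"]
  if (length(prior_ids) > 0L) {
    prior_cases <- make_quarter_case(prior_ids,
                                     -sample(1:4, length(prior_ids), replace = TRUE),
                                     "washout")
    cases <- dplyr::bind_rows(cases, prior_cases)
    diagnoses <- dplyr::bind_rows(diagnoses, tibble::tibble(
      case_id = prior_cases$case_id, icd_code = "F32.9", qualifier = "gesichert"
    ))
  }

  confirm_ids <- person_id[reason != "no_confirmation"]
  if (length(confirm_ids) > 0L) {
    confirm_cases <- make_quarter_case(confirm_ids,
                                       sample(1:2, length(confirm_ids), replace = TRUE),
                                       "confirm")
    cases <- dplyr::bind_rows(cases, confirm_cases)
    diagnoses <- dplyr::bind_rows(diagnoses, tibble::tibble(
      case_id = confirm_cases$case_id,
      icd_code = index_code[match(confirm_ids, person_id)],
      qualifier = "gesichert"
    ))
  }

  # planted comorbidities, attached to the confirmation case when the
  # person has one (ambulatory, confirmed qualifier), else to the index case
  comorb_codes <- c(alcohol = "F10.2", drugs = "F11.2", psychoses = "F20.0")
  host_case <- ifelse(person_id %in% confirm_ids,
                      paste0("C_confirm_", person_id),
                      paste0("C_idx_", person_id))
  for (flag in names(comorb_codes)) {
    hit <- stats::runif(n) < config$comorbidity_rates[[flag]]
    if (any(hit)) {
      diagnoses <- dplyr::bind_rows(diagnoses, tibble::tibble(
        case_id = host_case[hit],
        icd_code = comorb_codes[[flag]],
        qualifier = "gesichert"
      ))
    }
  }

  services <- simulate_services(person_id, pathway, index_start, config)

  bundle <- claims_bundle(persons, cases, diagnoses, services,
                          period_label = config$period)
  attr(bundle, "ground_truth") <- tibble::tibble(
    person_id = person_id,
    exclusion_reason = reason,
    severity = grade,
    pathway = pathway
  )
  attr(bundle, "scenario") <- config
  bundle
}

simulate_services <- function(person_id, pathway, index_start, config) {
  empty <- tibble::tibble(person_id = character(0),
                          service_date = as.Date(character(0)),
                          ebm_code = character(0),
                          unit_count = integer(0),
                          provider_specialty_group = character(0))
  has_services <- !is.na(pathway) & pathway != "no_pt_service"
  if (!any(has_services)) return(empty)

  idx <- which(has_services)
  variant_draw <- stats::runif(length(idx))
  seg_list <- mapply(pathway_variant_segments, pathway[idx],
                     MoreArgs = list(period = config$period),
                     variant_draw = variant_draw, SIMPLIFY = FALSE)
  seg_tbl <- tibble::tibble(
    person = rep(person_id[idx], lengths(seg_list)),
    window_start = rep(index_start[idx], lengths(seg_list)),
    seg_pos = unlist(lapply(lengths(seg_list), seq_len), use.names = FALSE),
    category = unlist(seg_list, use.names = FALSE),
    final_edge = rep(vapply(seg_list, final_edge_mean, numeric(1L),
                            config = config), lengths(seg_list))
  ) %>%
    dplyr::mutate(
      is_therapy = .data$category %in% c("kzt", "lzt", "akut"),
      n_sittings = 1L + stats::rpois(dplyr::n(),
                                     pmax(config$session_count_means[.data$category] - 1, 0))
    )

  sit <- seg_tbl[rep(seq_len(nrow(seg_tbl)), seg_tbl$n_sittings), ] %>%
    dplyr::group_by(.data$person, .data$seg_pos) %>%
    dplyr::mutate(sitting = dplyr::row_number()) %>%
    dplyr::ungroup()

  n_sit <- nrow(sit)
  first_of_person <- !duplicated(sit$person)
  first_of_segment <- sit$sitting == 1L
  spacing <- rgamma_days(n_sit, config$within_gap_mean, config$gap_shape,
                         lo = 1, hi = 91)
  transition <- first_of_segment & !first_of_person
  into_therapy <- transition & sit$is_therapy & !is.na(sit$final_edge)
  other_transition <- transition & !into_therapy
  spacing[other_transition] <- rgamma_days(sum(other_transition),
                                           config$default_transition_gap_mean,
                                           config$gap_shape, lo = 1)
  if (any(into_therapy)) {
    means <- sit$final_edge[into_therapy]
    spacing[into_therapy] <- pmax(round(stats::rgamma(
      length(means), shape = config$gap_shape, scale = means / config$gap_shape
    )), 1)
  }
  spacing[first_of_person] <- rgamma_days(sum(first_of_person),
                                          config$first_service_delay_mean,
                                          config$gap_shape, lo = 0)

  day <- stats::ave(spacing, sit$person, FUN = cumsum)
  # keep every service inside the 365-day window: rescale the rare
  # overflowing person (shrinking preserves the 91-day within-run bound)
  last_day <- stats::ave(day, sit$person, FUN = max)
  overflow <- last_day > 364
  for (iter in 1:5) {
    if (!any(overflow)) break
    shrink <- 364 / last_day[overflow]
    spacing[overflow] <- pmax(floor(spacing[overflow] * shrink),
                              ifelse(first_of_person[overflow], 0, 1))
    day <- stats::ave(spacing, sit$person, FUN = cumsum)
    last_day <- stats::ave(day, sit$person, FUN = max)
    overflow <- last_day > 364
  }
  if (any(overflow)) {
    spacing[overflow & !first_of_person] <- 1
    spacing[overflow & first_of_person] <- 0
    day <- stats::ave(spacing, sit$person, FUN = cumsum)
  }

  arm <- character(n_sit)
  two_arm <- sit$category %in% c("kzt", "lzt")
  arm[two_arm] <- sample(c("einzel", "gruppe"), sum(two_arm),
                         replace = TRUE, prob = c(0.85, 0.15))
  code <- ifelse(two_arm,
                 c(kzt_einzel = "KZT50", kzt_gruppe = "KZTG50",
                   lzt_einzel = "LZT50", lzt_gruppe = "LZTG50")[
                     paste0(sit$category, "_", arm)],
                 category_code[sit$category])

  tibble::tibble(
    person_id = sit$person,
    service_date = sit$window_start + day,
    ebm_code = unname(code),
    unit_count = ifelse(code %in% c("SPR25", "AKUT25"), 2L, 1L),
    provider_specialty_group = sample(c("51", "53", "58", "59", "60", "61", "68"),
                                      n_sit, replace = TRUE)
  )
}

#' Retrieve the generator ground truth of a synthetic bundle
#'
#' Returns the per-person intent recorded at generation time (exclusion
#' reason, severity grade, pathway). The bundle must have been produced
#' by [generate_bundle()] with exactly the given config; a mismatch is
#' an error.
#'
#' @param config The [scenario_config()] used for generation.
#' @param bundle The bundle returned by [generate_bundle()].
#' @return Tibble: `person_id`, `exclusion_reason`, `severity`,
#'   `pathway`.
#' @export
ground_truth <- function(config, bundle) {
  gt <- attr(bundle, "ground_truth")
  sc <- attr(bundle, "scenario")
  if (is.null(gt) || is.null(sc)) {
    stop("bundle carries no ground truth (not produced by generate_bundle)",
         call. = FALSE)
  }
  if (!identical(unclass(sc), unclass(config))) {
    stop("config does not match the one the bundle was generated with",
         call. = FALSE)
  }
  gt
}
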