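#' Pathway catalogues for the pre- and post-reform periods
#'
#' A pathway is an exact ordered sequence of service categories; a
#' member matches a pathway only when their full gap-truncated segment
#' sequence equals it. Short- and long-term therapy are matched on the
#' merged category (`kzt`, `lzt`), i.e. individual and group arms count
#' as one stage. The default catalogues are:
#'
#' * pre-reform: `1.1` probatorik - kzt; `1.2` probatorik - lzt;
#'   `1.3` probatorik only.
#' * post-reform: `2.1` (sprechstunde -) probatorik - kzt and `2.2`
#'   (sprechstunde -) probatorik - lzt, each with the leading
#'   consultation optional (two explicit variants sharing one id);
#'   `2.3` sprechstunde - akut; `2.4` sprechstunde - probatorik;
#'   `2.5` sprechstunde only.
#'
#' @param period `"pre"` or `"post"`.
#' @param definitions Optional custom catalogue: a tibble with columns
#'   `pathway_id` and `segments` (list column of character vectors over
#'   merged categories). Two definitions with an identical sequence are
#'   refused as ambiguous.
#' @return A tibble of class `pathway_catalogue` with columns
#'   `pathway_id`, `variant`, `segments`.
#' @export
pathway_catalogue <- function(period = c("pre", "post"), definitions = NULL) {
  period <- match.arg(period)
  if (is.null(definitions)) {
    definitions <- if (period == "pre") {
      tibble::tibble(
        pathway_id = c("1.1", "1.2", "1.3"),
        segments = list(c("probatorik", "kzt"),
                        c("probatorik", "lzt"),
                        "probatorik")
      )
    } else {
      tibble::tibble(
        pathway_id = c("2.1", "2.1", "2.2", "2.2", "2.3", "2.4", "2.5"),
        segments = list(c("sprechstunde", "probatorik", "kzt"),
                        c("probatorik", "kzt"),
                        c("sprechstunde", "probatorik", "lzt"),
                        c("probatorik", "lzt"),
                        c("sprechstunde", "akut"),
                        c("sprechstunde", "probatorik"),
                        "sprechstunde")
      )
    }
  }
  stopifnot(all(c("pathway_id", "segments") %in% names(definitions)))
  ok_seg <- vapply(definitions$segments, function(s) {
    length(s) > 0L && !any(s[-1L] == s[-length(s)]) &&
      all(s %in% unique(merge_therapy_arm(service_categories)))
  }, logical(1L))
  if (!all(ok_seg)) {
    stop("invalid pathway definition: empty sequence, repeated consecutive ",
         "category, or unknown category", call. = FALSE)
  }
  keys <- vapply(definitions$segments, paste, character(1L), collapse = ">")
  if (anyDuplicated(keys) > 0L) {
    stop("ambiguous catalogue: two definitions share the sequence ",
         keys[duplicated(keys)][[1L]], call. = FALSE)
  }
  out <- definitions %>%
    dplyr::group_by(.data$pathway_id) %>%
    dplyr::mutate(variant = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::select("pathway_id", "variant", "segments")
  attr(out, "period") <- period
  class(out) <- c("pathway_catalogue", class(out))
  out
}

#' Truncate service series at same-service gaps over 91 days
#'
#' Per person and per merged category, keeps the maximal prefix of that
#' category's date-ordered event series in which consecutive events are
#' at most `max_gap` days apart; a gap of more than `max_gap` days to
#' the next same-type service drops that event and everything after it
#' in the category. Dropped events are counted in the attribute
#' `truncation_log` (`person_id`, `category`, `n_dropped`). The
#' operation is idempotent.
#'
#' @param events Service-event tibble from [map_services()].
#' @param max_gap Maximum allowed gap in days between consecutive
#'   same-type services (default 91; a gap of exactly 91 days is kept).
#' @return The truncated event tibble, same columns as the input.
#' @export
truncate_gaps <- function(events, max_gap = 91) {
  marked <- events %>%
    dplyr::mutate(merged = merge_therapy_arm(as.character(.data$category))) %>%
    dplyr::group_by(.data$person_id, .data$merged) %>%
    dplyr::arrange(.data$date, .by_group = TRUE) %>%
    dplyr::mutate(
      gap = as.numeric(.data$date - dplyr::lag(.data$date)),
      keep = cumsum(dplyr::coalesce(.data$gap, 0) > max_gap) == 0L
    ) %>%
    dplyr::ungroup()
  log <- marked %>%
    dplyr::filter(!.data$keep) %>%
    dplyr::count(.data$person_id, category = .data$merged, name = "n_dropped")
  out <- marked %>%
    dplyr::filter(.data$keep) %>%
    dplyr::select(-"merged", -"gap", -"keep") %>%
    dplyr::arrange(.data$person_id, .data$date, .data$category)
  attr(out, "truncation_log") <- log
  out
}

#' Collapse events into pathway segments
#'
#' Orders each person's gap-truncated events by date (same-day ties by
#' declared category order) and collapses consecutive runs of one merged
#' category into a segment with summed sessions, first/last date and
#' duration in days (0 for a single-event segment). A person whose
#' sequence revisits a category after an intervening other category is
#' flagged `interleaved`; such sequences never match a catalogue
#' pathway.
#'
#' @param events Gap-truncated service events, see [truncate_gaps()].
#' @return Tibble with one row per (person, segment): `person_id`,
#'   `seg_index`, `category` (merged), `n_sessions`, `first_date`,
#'   `last_date`, `duration_days`, `gap_before` (days since the previous
#'   segment's last event; `NA` for the first segment), `interleaved`.
#' @export
compress_to_segments <- function(events) {
  events %>%
    dplyr::mutate(merged = merge_therapy_arm(as.character(.data$category))) %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::arrange(.data$date, .data$category, .by_group = TRUE) %>%
    dplyr::mutate(seg_index = cumsum(
      dplyr::coalesce(.data$merged != dplyr::lag(.data$merged), TRUE)
    )) %>%
    dplyr::group_by(.data$person_id, .data$seg_index) %>%
    dplyr::summarise(
      category = .data$merged[[1L]],
      n_sessions = sum(.data$sessions),
      first_date = min(.data$date),
      last_date = max(.data$date),
      .groups = "drop_last"
    ) %>%
    dplyr::mutate(
      duration_days = as.numeric(.data$last_date - .data$first_date),
      gap_before = as.numeric(.data$first_date - dplyr::lag(.data$last_date)),
      interleaved = anyDuplicated(.data$category) > 0L
    ) %>%
    dplyr::ungroup()
}

#' Match segment sequences against a pathway catalogue
#'
#' Assigns each person the unique catalogue pathway whose category
#' sequence equals the person's full segment sequence; matching is exact
#' and exhaustive (not longest-prefix). Interleaved sequences and
#' sequences absent from the catalogue are `"unmatched"`.
#'
#' @param segments Segment tibble from [compress_to_segments()].
#' @param catalogue A [pathway_catalogue()].
#' @return One row per person: `person_id`, `pathway_id` (or
#'   `"unmatched"`), `n_segments`, `interleaved`.
#' @export
match_pathway <- function(segments, catalogue) {
  stopifnot(inherits(catalogue, "pathway_catalogue"))
  keys <- tibble::tibble(
    sequence_key = vapply(catalogue$segments, paste, character(1L), collapse = ">"),
    pathway_id = catalogue$pathway_id
  )
  segments %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::arrange(.data$seg_index, .by_group = TRUE) %>%
    dplyr::summarise(
      sequence_key = paste(.data$category, collapse = ">"),
      n_segments = dplyr::n(),
      interleaved = .data$interleaved[[1L]],
      .groups = "drop"
    ) %>%
    dplyr::left_join(keys, by = "sequence_key") %>%
    dplyr::mutate(pathway_id = dplyr::if_else(
      .data$interleaved | is.na(.data$pathway_id), "unmatched", .data$pathway_id
    )) %>%
    dplyr::select("person_id", "pathway_id", "sequence_key", "n_segments",
                  "interleaved")
}

#' Per-pathway stage statistics
#'
#' For each pathway and stage: number of members, median/mean/SD of
#' per-stage session counts and treatment durations (days between first
#' and last same-type service), mean transition gap from the previous
#' stage, and the cumulative mean timeline (sum of mean durations and
#' mean gaps of stages 1..k). Pathway-level shares are computed against
#' the denominator of members with at least one psychotherapeutic
#' service.
#'
#' Pathways whose id covers two catalogue variants (an optional leading
#' consultation) are reported per variant, identified by the
#' `sequence_key` column, so stage positions line up within a row
#' group and the cumulative timeline is summed along one concrete
#' sequence.
#'
#' @param assignments Tibble from [match_pathway()].
#' @param segments Tibble from [compress_to_segments()].
#' @return A list with `pathways` (one row per pathway: `pathway_id`,
#'   `n`, `share_pct` of the at-least-one-service denominator) and
#'   `stages` (one row per pathway variant stage with the statistics
#'   above).
#' @export
pathway_statistics <- function(assignments, segments) {
  n_any <- nrow(assignments)
  pathways <- assignments %>%
    dplyr::count(.data$pathway_id, name = "n") %>%
    dplyr::mutate(share_pct = percent(.data$n, n_any))
  stages <- segments %>%
    dplyr::inner_join(dplyr::select(assignments, "person_id", "pathway_id",
                                    "sequence_key"),
                      by = "person_id") %>%
    dplyr::filter(.data$pathway_id != "unmatched") %>%
    dplyr::group_by(.data$pathway_id, .data$sequence_key, .data$seg_index,
                    .data$category) %>%
    dplyr::summarise(
      n = dplyr::n(),
      sessions_median = stats::median(.data$n_sessions),
      sessions_mean = mean(.data$n_sessions),
      sessions_sd = stats::sd(.data$n_sessions),
      duration_median = stats::median(.data$duration_days),
      duration_mean = mean(.data$duration_days),
      duration_sd = stats::sd(.data$duration_days),
      gap_before_mean = mean(.data$gap_before),
      .groups = "drop"
    ) %>%
    dplyr::group_by(.data$pathway_id, .data$sequence_key) %>%
    dplyr::arrange(.data$seg_index, .by_group = TRUE) %>%
    dplyr::mutate(cumulative_mean_days = cumsum(
      .data$duration_mean + dplyr::coalesce(.data$gap_before_mean, 0)
    )) %>%
    dplyr::ungroup()
  list(pathways = pathways, stages = stages)
}
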