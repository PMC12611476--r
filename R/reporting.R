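#' Rounding and percentage primitives for report tables
#'
#' All printed report numbers use round-half-up (not banker's
#' rounding): `round_half_up(16.85, 1)` is 16.9. `percent()` renders a
#' count ratio as a percentage with one decimal; the raw counts are kept
#' alongside in report tables. `treatment_frequency()` is the mean
#' treatment duration divided by the mean session count, i.e. the mean
#' number of days per delivered session along a pathway stage, rounded
#' to one decimal. `mean_difference()` is the post-minus-pre difference
#' of two means at one decimal.
#'
#' @param x Numeric vector.
#' @param digits Number of decimals.
#' @param numerator,denominator Counts.
#' @param mean_duration_days,mean_sessions Stage means.
#' @param mean_pre,mean_post Period means.
#' @return Numeric vector(s); `percent()` with a zero denominator gives
#'   `NA` with a warning.
#' @examples
#' percent(26195, 149941)   # 17.5
#' treatment_frequency(63.1, 3.8)  # 16.6
#' mean_difference(72.50, 89.35)   # 16.9
#' @name report_arithmetic
NULL

#' @rdname report_arithmetic
#' @export
round_half_up <- function(x, digits = 1) {
  # epsilon guard against binary representation error (e.g. 16.85 * 10
  # is stored as 168.4999...), so true halves always round up
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' @rdname report_arithmetic
#' @export
percent <- function(numerator, denominator) {
  out <- rep(NA_real_, length(numerator))
  bad <- denominator <= 0
  if (any(bad)) {
    warning("percent undefined for zero denominator", call. = FALSE)
  }
  out[!bad] <- round_half_up(100 * numerator[!bad] / denominator[!bad], 1)
  out
}

#' @rdname report_arithmetic
#' @export
treatment_frequency <- function(mean_duration_days, mean_sessions) {
  round_half_up(mean_duration_days / mean_sessions, 1)
}

#' @rdname report_arithmetic
#' @export
mean_difference <- function(mean_pre, mean_post, digits = 1) {
  round_half_up(mean_post - mean_pre, digits)
}

count_share_rows <- function(values, variable, levels) {
  n_total <- length(values)
  tibble::tibble(variable = variable,
                 level = factor(values, levels = levels)) %>%
    dplyr::count(.data$variable, .data$level, .drop = FALSE) %>%
    dplyr::mutate(level = as.character(.data$level),
                  pct = percent(.data$n, n_total))
}

#' Demographic / clinical cohort table for one period pair
#'
#' Builds the sociodemographic comparison table: age (mean, SD), sex,
#' urbanicity, severity, diagnosis site and the three mental
#' comorbidity flags, with counts and percentages per period and a
#' Mann-Whitney p-value plus scale-appropriate effect size per
#' variable.
#'
#' @param cohort_pre,cohort_post Cohort tibbles from [select_cohort()].
#' @return A list with `rows` (variable, level, n/pct per period) and
#'   `comparisons` (one row per variable from [compare_groups()]).
#' @export
cohort_table <- function(cohort_pre, cohort_post) {
  lv <- list(
    sex = c("female", "male"),
    urbanicity = c("stadt", "mischkreis", "land"),
    severity = rev(severity_levels),
    diagnosis_site = c("hospital", "ambulatory_hausarzt",
                       "ambulatory_psychotherapeut", "ambulatory_other")
  )
  one_period <- function(cohort) {
    dplyr::bind_rows(
      count_share_rows(as.character(cohort$sex), "sex", lv$sex),
      count_share_rows(as.character(cohort$urbanicity), "urbanicity", lv$urbanicity),
      count_share_rows(as.character(cohort$severity), "severity", lv$severity),
      count_share_rows(cohort$diagnosis_site, "diagnosis_site", lv$diagnosis_site),
      tibble::tibble(variable = "comorbidity",
                     level = c("alcohol", "drugs", "psychoses"),
                     n = c(sum(cohort$alcohol), sum(cohort$drugs),
                           sum(cohort$psychoses))) %>%
        dplyr::mutate(pct = percent(.data$n, nrow(cohort))),
      tibble::tibble(variable = "age", level = "mean_sd",
                     n = nrow(cohort), pct = NA_real_,
                     mean = mean(cohort$age_at_index),
                     sd = stats::sd(cohort$age_at_index))
    )
  }
  rows <- dplyr::full_join(
    one_period(cohort_pre), one_period(cohort_post),
    by = c("variable", "level"), suffix = c("_pre", "_post")
  )
  comparisons <- dplyr::bind_rows(
    compare_groups(cohort_pre$age_at_index, cohort_post$age_at_index,
                   "age", "metric"),
    compare_groups(as.character(cohort_pre$sex), as.character(cohort_post$sex),
                   "sex", "binary"),
    compare_groups(as.character(cohort_pre$urbanicity),
                   as.character(cohort_post$urbanicity), "urbanicity", "nominal"),
    compare_groups(factor(cohort_pre$severity, levels = severity_levels),
                   factor(cohort_post$severity, levels = severity_levels),
                   "severity", "nominal"),
    compare_groups(cohort_pre$diagnosis_site == "hospital",
                   cohort_post$diagnosis_site == "hospital",
                   "diagnosis_site_hospital", "binary"),
    compare_groups(cohort_pre$alcohol, cohort_post$alcohol, "alcohol", "binary"),
    compare_groups(cohort_pre$drugs, cohort_post$drugs, "drugs", "binary"),
    compare_groups(cohort_pre$psychoses, cohort_post$psychoses,
                   "psychoses", "binary")
  )
  list(rows = rows, comparisons = comparisons)
}

run_period <- function(input, index_quarter, period, ruleset, code_map,
                       catalogue = NULL) {
  bundle <- if (inherits(input, "claims_bundle")) {
    input
  } else if (inherits(input, "scenario_config")) {
    generate_bundle(input)
  } else {
    stop("period input must be a claims_bundle or scenario_config",
         call. = FALSE)
  }
  if (is.null(index_quarter)) {
    if (!inherits(input, "scenario_config")) {
      stop("index_quarter required when passing a bundle", call. = FALSE)
    }
    index_quarter <- c(input$index_year, input$index_quarter)
  }
  if (is.null(catalogue)) catalogue <- pathway_catalogue(period)
  sel <- select_cohort(bundle, index_quarter, ruleset)
  events <- map_services(sel$cohort, bundle, code_map)
  events <- truncate_gaps(events)
  segments <- compress_to_segments(events)
  assignments <- match_pathway(segments, catalogue)
  list(
    bundle = bundle,
    cohort = sel$cohort,
    exclusions = sel$exclusions,
    events = events,
    segments = segments,
    assignments = assignments,
    pathway_stats = pathway_statistics(assignments, segments),
    intervals = compute_intervals(sel$cohort, events)
  )
}

#' Run the full pre/post pathway pipeline
#'
#' Orchestrates both periods end to end: cohort selection, service
#' mapping and gap truncation, segment compression, pathway matching
#' and statistics, interval computation, and the pre/post comparison
#' tables. Inputs can be `claims_bundle`s (real-format data) or
#' [scenario_config()]s (synthetic data, generated on the fly).
#'
#' @param pre,post A `claims_bundle` or `scenario_config` per period.
#' @param index_quarter_pre,index_quarter_post Index quarters (only
#'   needed for bundles; configs carry their own).
#' @param ruleset A [selection_ruleset()].
#' @param code_map A code map tibble, see [default_code_map()].
#' @return An object of class `pt_report`: a list with per-period
#'   results (`pre`, `post`: cohort, exclusions, events, segments,
#'   assignments, pathway_stats, intervals), the `cohort_table`, the
#'   `interval_table` (overall / by therapy type / by severity, per
#'   period), `interval_comparison`, and `attrition`. Has
#'   [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
run_pipeline <- function(pre, post,
                         index_quarter_pre = NULL, index_quarter_post = NULL,
                         ruleset = selection_ruleset(),
                         code_map = default_code_map()) {
  res_pre <- run_period(pre, index_quarter_pre, "pre", ruleset, code_map)
  res_post <- run_period(post, index_quarter_post, "post", ruleset, code_map)

  interval_table <- dplyr::bind_rows(
    lapply(c(pre = "pre", post = "post"), function(p) {
      res <- if (p == "pre") res_pre else res_post
      dplyr::bind_rows(
        dplyr::mutate(interval_summary(res$intervals, "none"), strata = "overall"),
        dplyr::mutate(interval_summary(res$intervals, "therapy_type"),
                      strata = "therapy_type"),
        dplyr::mutate(interval_summary(res$intervals, "severity"),
                      strata = "severity")
      ) %>% dplyr::mutate(period = p, .before = 1L)
    })
  )
  interval_comparison <- compare_groups(
    res_pre$intervals$gap_days, res_post$intervals$gap_days,
    "contact_to_therapy_gap", "metric"
  )
  attrition <- dplyr::bind_rows(
    dplyr::mutate(dplyr::count(res_pre$exclusions, .data$reason), period = "pre"),
    dplyr::mutate(dplyr::count(res_post$exclusions, .data$reason), period = "post")
  )
  structure(
    list(
      pre = res_pre,
      post = res_post,
      cohort_table = cohort_table(res_pre$cohort, res_post$cohort),
      interval_table = interval_table,
      interval_comparison = interval_comparison,
      attrition = attrition
    ),
    class = "pt_report"
  )
}

#' @export
print.pt_report <- function(x, ...) {
  g <- glance(x)
  cat("<pt_report>\n")
  cat(sprintf("  cohort: %d (pre) / %d (post)\n", g$n_pre, g$n_post))
  cat(sprintf("  with >=1 pt service: %.1f%% / %.1f%%\n",
              g$share_any_pt_pre, g$share_any_pt_post))
  cat(sprintf("  mean contact-to-therapy gap: %.1f d / %.1f d\n",
              g$mean_gap_pre, g$mean_gap_post))
  invisible(x)
}

#' @export
glance.pt_report <- function(x, ...) {
  ov <- dplyr::filter(x$interval_table, .data$strata == "overall")
  tibble::tibble(
    n_pre = nrow(x$pre$cohort),
    n_post = nrow(x$post$cohort),
    share_any_pt_pre = percent(nrow(x$pre$assignments), nrow(x$pre$cohort)),
    share_any_pt_post = percent(nrow(x$post$assignments), nrow(x$post$cohort)),
    n_intervals_pre = ov$n[ov$period == "pre"],
    n_intervals_post = ov$n[ov$period == "post"],
    mean_gap_pre = ov$mean[ov$period == "pre"],
    mean_gap_post = ov$mean[ov$period == "post"],
    gap_difference = mean_difference(ov$mean[ov$period == "pre"],
                                     ov$mean[ov$period == "post"])
  )
}

#' @export
tidy.pt_report <- function(x, ...) {
  dplyr::bind_rows(x$cohort_table$comparisons, x$interval_comparison)
}

#' Write all report tables as CSV files
#'
#' Emits `cohort_table.csv`, `comparisons.csv`, `interval_table.csv`,
#' `pathway_stats_pre.csv`, `pathway_stats_post.csv`,
#' `pathway_shares_pre.csv`, `pathway_shares_post.csv` and
#' `attrition.csv` into a directory, so every report number is
#' recomputable from emitted intermediates.
#'
#' @param report A `pt_report`.
#' @param directory_path Target directory (created if absent).
#' @return Invisibly, `directory_path`.
#' @export
write_report <- function(report, directory_path) {
  stopifnot(inherits(report, "pt_report"))
  if (!dir.exists(directory_path)) dir.create(directory_path, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(directory_path, paste0(name, ".csv")),
                     progress = FALSE)
  }
  w(report$cohort_table$rows, "cohort_table")
  w(tidy(report), "comparisons")
  w(report$interval_table, "interval_table")
  w(report$pre$pathway_stats$stages, "pathway_stats_pre")
  w(report$post$pathway_stats$stages, "pathway_stats_post")
  w(report$pre$pathway_stats$pathways, "pathway_shares_pre")
  w(report$post$pathway_stats$pathways, "pathway_shares_post")
  w(report$attrition, "attrition")
  invisible(directory_path)
}
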