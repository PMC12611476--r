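test_that("the 91-day same-service gap rule keeps the boundary and truncates beyond", {
  # gap of 100 days drops the later probatory service
  ev <- fx_events("p", c(0, 30, 130), rep("probatorik", 3))
  out <- truncate_gaps(ev)
  expect_equal(as.numeric(out$date - fx_origin), c(0, 30))
  log <- attr(out, "truncation_log")
  expect_equal(log$n_dropped, 1L)
  # exactly 91 days is allowed ("more than 91" truncates)
  ev <- fx_events("p", c(0, 91), rep("kzt_einzel", 2))
  expect_equal(nrow(truncate_gaps(ev)), 2L)
  ev <- fx_events("p", c(0, 92), rep("kzt_einzel", 2))
  expect_equal(nrow(truncate_gaps(ev)), 1L)
  # single events per category are untouched
  ev <- fx_events("p", c(0, 200), c("probatorik", "kzt_einzel"))
  expect_equal(nrow(truncate_gaps(ev)), 2L)
  # individual and group arms count as the same service type
  ev <- fx_events("p", c(0, 50, 142), c("kzt_einzel", "kzt_gruppe", "kzt_einzel"))
  expect_equal(nrow(truncate_gaps(ev)), 2L)
})

test_that("gap truncation is idempotent on random event series", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(1:12, 1)
    ev <- fx_events("p", sort(sample(0:364, n)),
                    sample(service_categories, n, replace = TRUE))
    once <- truncate_gaps(ev)
    twice <- truncate_gaps(once)
    expect_equal(fx_strip_log(twice), fx_strip_log(once))
  }
})

test_that("segment compression reproduces the worked arithmetic example", {
  ev <- fx_events("p", c(0, 14, 21, 35, 60, 67),
                  c("sprechstunde", "probatorik", "probatorik", "probatorik",
                    "kzt_einzel", "kzt_gruppe"))
  seg <- compress_to_segments(ev)
  expect_equal(seg$category, c("sprechstunde", "probatorik", "kzt"))
  expect_equal(seg$n_sessions, c(1, 3, 2))
  expect_equal(seg$duration_days, c(0, 21, 7))
  expect_equal(seg$gap_before, c(NA, 14, 25))
  expect_false(any(seg$interleaved))
  # single-service treatment has duration 0 days
  seg1 <- compress_to_segments(fx_events("p", 10, "probatorik"))
  expect_equal(seg1$duration_days, 0)
  expect_equal(seg1$n_sessions, 1)
  # revisiting a category flags the sequence as interleaved
  seg2 <- compress_to_segments(
    fx_events("p", c(0, 10, 20), c("probatorik", "kzt_einzel", "probatorik"))
  )
  expect_true(all(seg2$interleaved))
})

test_that("pathway matching is exact and exhaustive against the catalogue", {
  pre <- pathway_catalogue("pre")
  post <- pathway_catalogue("post")
  match_one <- function(days, cats, catalogue) {
    seg <- compress_to_segments(fx_events("p", days, cats))
    match_pathway(seg, catalogue)$pathway_id
  }
  expect_equal(match_one(c(0, 56), c("probatorik", "kzt_einzel"), pre), "1.1")
  expect_equal(match_one(c(0, 56), c("probatorik", "lzt_gruppe"), pre), "1.2")
  expect_equal(match_one(0, "probatorik", pre), "1.3")
  expect_equal(match_one(c(0, 45), c("sprechstunde", "akut"), post), "2.3")
  # the acute-treatment pathway does not exist pre-reform
  expect_equal(match_one(c(0, 45), c("sprechstunde", "akut"), pre), "unmatched")
  # both variants of the optional leading consultation share one id
  expect_equal(match_one(c(0, 14, 60), c("sprechstunde", "probatorik", "kzt_einzel"),
                         post), "2.1")
  expect_equal(match_one(c(0, 60), c("probatorik", "kzt_einzel"), post), "2.1")
  # exact matching, not longest-prefix: a trailing extra stage unmatches
  expect_equal(match_one(c(0, 56, 120), c("probatorik", "kzt_einzel", "lzt_einzel"),
                         pre), "unmatched")
  # interleaved sequences never match
  expect_equal(match_one(c(0, 10, 20), c("probatorik", "kzt_einzel", "probatorik"),
                         pre), "unmatched")
})

test_that("an ambiguous catalogue is refused at construction", {
  expect_error(
    pathway_catalogue("pre", tibble::tibble(
      pathway_id = c("a", "b"),
      segments = list(c("probatorik", "kzt"), c("probatorik", "kzt"))
    )),
    "ambiguous"
  )
  expect_error(
    pathway_catalogue("pre", tibble::tibble(
      pathway_id = "a", segments = list(c("kzt", "kzt"))
    )),
    "invalid pathway definition"
  )
})

test_that("matcher agrees with brute-force sequence comparison on short series", {
  set.seed(202)
  for (catalogue in list(pathway_catalogue("pre"), pathway_catalogue("post"))) {
    for (i in 1:200) {
      n <- sample(1:6, 1)
      cats <- sample(service_categories, n, replace = TRUE)
      days <- sort(sample(0:300, n))
      # keep same-type gaps within 91 days so truncation cannot interfere
      ev <- fx_events("p", round(days * 0.3), cats)
      got <- match_pathway(compress_to_segments(ev), catalogue)$pathway_id
      cats_in_order <- as.character(dplyr::arrange(ev, date, category)$category)
      expect_equal(got, fx_brute_match(cats_in_order, catalogue))
    }
  }
})

test_that("pathway statistics aggregate stage arithmetic correctly", {
  ev <- dplyr::bind_rows(
    fx_events("a", c(0, 30, 90), c("probatorik", "probatorik", "kzt_einzel")),
    fx_events("b", c(10, 76), c("probatorik", "kzt_einzel")),
    fx_events("c", 5, "sprechstunde")  # unmatched pre-reform
  )
  seg <- compress_to_segments(ev)
  asn <- match_pathway(seg, pathway_catalogue("pre"))
  st <- pathway_statistics(asn, seg)
  expect_equal(sum(st$pathways$n), 3L)  # partition incl. unmatched
  p11 <- dplyr::filter(st$stages, pathway_id == "1.1")
  # mean pre-therapy spans: a waits 60 d after the last probatory session,
  # b waits 66 d -> mean transition gap 63
  expect_equal(p11$gap_before_mean[p11$category == "kzt"], 63)
  expect_equal(p11$n, c(2L, 2L))
  expect_equal(p11$sessions_mean, c(1.5, 1))
  # cumulative timeline: mean probatory duration (15) + mean gap (63)
  expect_equal(p11$cumulative_mean_days, c(15, 78))
  # shares use the >=1-service denominator
  expect_equal(st$pathways$share_pct[st$pathways$pathway_id == "1.1"],
               percent(2, 3))
})
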