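test_that("bundle construction preserves counts and validates integrity", {
  b <- fx_tiny_bundle()
  expect_s3_class(b, "claims_bundle")
  expect_equal(nrow(b$persons), 2L)
  expect_equal(nrow(b$cases), 3L)
  expect_equal(nrow(b$diagnoses), 4L)
  expect_equal(nrow(b$services), 5L)

  # empty services table is allowed
  b0 <- claims_bundle(b$persons, b$cases, b$diagnoses, b$services[0, ], "pre")
  expect_equal(nrow(b0$services), 0L)

  # dangling foreign keys are integrity errors naming the offender
  expect_error(
    claims_bundle(b$persons, b$cases,
                  dplyr::bind_rows(b$diagnoses, fx_dx("ghost", "F32.0")),
                  b$services, "pre"),
    "integrity error.*ghost"
  )
  expect_error(
    claims_bundle(b$persons, b$cases, b$diagnoses,
                  dplyr::bind_rows(b$services,
                                   fx_service("nobody", "2016-02-01", "PROB50")),
                  "pre"),
    "integrity error.*nobody"
  )
  expect_error(
    claims_bundle(b$persons[0, ], b$cases, b$diagnoses, b$services, "pre"),
    "integrity error"
  )
})

test_that("schema violations are rejected with the table and column named", {
  b <- fx_tiny_bundle()
  expect_error(
    claims_bundle(dplyr::select(b$persons, -"sex"), b$cases, b$diagnoses,
                  b$services, "pre"),
    "persons.*sex"
  )
  bad_dates <- dplyr::mutate(b$cases, end_date = start_date - 1L)
  expect_error(
    claims_bundle(b$persons, bad_dates, b$diagnoses, b$services, "pre"),
    "start_date > end_date"
  )
  stray <- dplyr::mutate(b$cases,
                         start_date = as.Date("2015-12-20"),
                         end_date = as.Date("2015-12-25"))
  expect_error(
    claims_bundle(b$persons, stray, b$diagnoses, b$services, "pre"),
    "outside their calendar quarter"
  )
  bad_icd <- dplyr::mutate(b$diagnoses, icd_code = "32F")
  expect_error(
    claims_bundle(b$persons, b$cases, bad_icd, b$services, "pre"),
    "icd_code"
  )
})

test_that("write/read round trip is the identity, including non-ASCII ids", {
  b <- fx_tiny_bundle()
  b$persons$person_id[1] <- "pö-1"
  b$cases$person_id[b$cases$person_id == "p1"] <- "pö-1"
  b$services$person_id[b$services$person_id == "p1"] <- "pö-1"
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir, "pre")
  for (tbl in c("persons", "cases", "diagnoses", "services")) {
    expect_equal(as.data.frame(b2[[tbl]]), as.data.frame(b[[tbl]]),
                 ignore_attr = TRUE)
  }
  expect_identical(b2$period_label, b$period_label)
})

test_that("reading refuses missing tables and writing refuses invalid bundles", {
  dir <- withr::local_tempdir()
  expect_error(read_bundle(dir, "pre"), "persons")
  b <- fx_tiny_bundle()
  write_bundle(b, dir)
  file.remove(file.path(dir, "services.csv"))
  expect_error(read_bundle(dir, "pre"), "services")

  broken <- b
  broken$diagnoses <- dplyr::bind_rows(b$diagnoses, fx_dx("ghost", "F32.0"))
  expect_error(write_bundle(broken, withr::local_tempdir()), "integrity error")
})

test_that("quarter arithmetic matches the (year, ceil(month/3)) definition", {
  dates <- as.Date("2014-01-01") + 0:2000
  lt <- as.POSIXlt(dates)
  expect_identical(date_quarter_index(dates),
                   quarter_index(lt$year + 1900L, ceiling((lt$mon + 1L) / 3)))
  # quarter start/end bracket every date of the quarter, half-open
  qi <- date_quarter_index(dates)
  y <- index_quarter_year(qi)
  q <- index_quarter_number(qi)
  expect_true(all(dates >= quarter_start(y, q)))
  expect_true(all(dates < quarter_end_exclusive(y, q)))
  expect_identical(parse_quarter("2016Q1"), list(year = 2016L, quarter = 1L))
  expect_error(parse_quarter("2016-1"), "2016Q1")
})
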