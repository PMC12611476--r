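#' Calendar-quarter helpers
#'
#' Ambulatory billing groups services into treatment cases per calendar
#' quarter, so the whole pipeline reasons in (year, quarter) pairs. A
#' quarter is represented externally as a pair or a label like `"2016Q1"`,
#' and internally as a single integer index (`year * 4 + quarter - 1`) so
#' that washout arithmetic is plain subtraction.
#'
#' @param year,quarter Integer calendar year and quarter (1--4).
#' @param x A `Date` vector.
#' @param label A string like `"2016Q1"`.
#' @param qi A quarter index as returned by `quarter_index()`.
#' @return `quarter_index()` returns an integer; `quarter_start()` and
#'   `quarter_end_exclusive()` return `Date`s; `date_quarter_index()` maps
#'   dates to indices; `parse_quarter()` returns a list with `year` and
#'   `quarter`.
#' @examples
#' quarter_index(2016, 1)
#' quarter_start(2016, 3)
#' date_quarter_index(as.Date("2016-05-15"))
#' @name quarters
NULL

#' @rdname quarters
#' @export
quarter_index <- function(year, quarter) {
  stopifnot(all(quarter %in% 1:4))
  as.integer(year) * 4L + as.integer(quarter) - 1L
}

#' @rdname quarters
#' @export
quarter_start <- function(year, quarter) {
  stopifnot(all(quarter %in% 1:4))
  as.Date(sprintf("%04d-%02d-01", year, (quarter - 1L) * 3L + 1L))
}

#' @rdname quarters
#' @export
quarter_end_exclusive <- function(year, quarter) {
  nxt_y <- ifelse(quarter == 4L, year + 1L, year)
  nxt_q <- ifelse(quarter == 4L, 1L, quarter + 1L)
  quarter_start(nxt_y, nxt_q)
}

#' @rdname quarters
#' @export
date_quarter_index <- function(x) {
  stopifnot(inherits(x, "Date"))
  lt <- as.POSIXlt(x)
  quarter_index(lt$year + 1900L, (lt$mon %/% 3L) + 1L)
}

#' @rdname quarters
#' @export
index_quarter_year <- function(qi) qi %/% 4L

#' @rdname quarters
#' @export
index_quarter_number <- function(qi) qi %% 4L + 1L

#' @rdname quarters
#' @export
parse_quarter <- function(label) {
  if (is.list(label) && all(c("year", "quarter") %in% names(label))) {
    return(list(year = as.integer(label$year), quarter = as.integer(label$quarter)))
  }
  if (is.numeric(label) && length(label) == 2L) {
    return(list(year = as.integer(label[[1L]]), quarter = as.integer(label[[2L]])))
  }
  m <- regmatches(label, regexec("^([0-9]{4})Q([1-4])$", label))[[1L]]
  if (length(m) != 3L) {
    stop("quarter label must look like '2016Q1', got: ", label, call. = FALSE)
  }
  list(year = as.integer(m[[2L]]), quarter = as.integer(m[[3L]]))
}
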