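#' Mann-Whitney U test for two independent samples
#'
#' Computes the U statistic from rank sums with midranks for ties; the
#' two-sided p-value comes from the exact null distribution of U when
#' `n_x * n_y <= exact_limit` and there are no ties, and otherwise from
#' the normal approximation with tie-corrected variance and continuity
#' correction. U is reported for the first sample (side convention:
#' `U = sum(rank(x)) - n_x (n_x + 1) / 2`), so e.g. `x = 1:3` against
#' `y = 4:6` gives `U = 0`. When all values across both samples are
#' identical the variance is zero and p is 1, with a warning.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_limit Use the exact distribution when `n_x * n_y` is at
#'   most this and there are no ties (default 400).
#' @return An object of class `ptpaths_mwu`: a list with `statistic`
#'   (U), `p_value`, `method` (`"exact"` or `"normal_approx"`), `n_x`,
#'   `n_y`. Has a [generics::tidy()] method.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 400) {
  stopifnot(length(x) > 0L, length(y) > 0L,
            is.numeric(x) || is.ordered(x) || is.integer(x),
            !anyNA(x), !anyNA(y))
  x <- as.numeric(x)
  y <- as.numeric(y)
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)

  if (!has_ties && nx * ny <= exact_limit) {
    p_lo <- stats::pwilcox(u, nx, ny)
    p_hi <- 1 - stats::pwilcox(u - 1, nx, ny)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      warning("zero variance: all values identical across both samples",
              call. = FALSE)
      p <- 1
      method <- "degenerate"
    } else {
      # continuity correction pulls |U - mu| toward the mean by 0.5
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      method <- "normal_approx"
    }
  }
  structure(
    list(statistic = u, p_value = p, method = method, n_x = nx, n_y = ny),
    class = "ptpaths_mwu"
  )
}

#' @export
print.ptpaths_mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (%s), n = %d/%d, two-sided p = %.4g\n",
              x$statistic, x$method, x$n_x, x$n_y, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ptpaths_mwu <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 method = x$method, n_x = x$n_x, n_y = x$n_y)
}

#' Effect-size coefficients: phi, Cramer's V, eta
#'
#' `phi_coefficient()` computes the signed phi coefficient
#' `(ad - bc) / sqrt(r1 r2 c1 c2)` of a 2x2 count table (sign
#' convention: first row = first group, first column = reference
#' category). `cramers_v()` computes `sqrt(chi2 / (n (min(r, c) - 1)))`
#' from the Pearson chi-squared statistic without continuity correction.
#' `eta_coefficient()` computes `sqrt(SS_between / SS_total)` for a
#' metric variable against group labels. Cramer's V and eta lie in
#' \[0, 1\]; phi in \[-1, 1\]; `|phi|` equals V on any 2x2 table.
#' Degenerate input (a zero margin, or zero total sum of squares) gives
#' `NA` with a warning rather than propagating `NaN`.
#'
#' @param counts A count matrix (2x2 for phi; r x c for Cramer's V).
#' @param groups Group labels (eta).
#' @param values Numeric values (eta).
#' @return A single numeric value (or `NA` if undefined).
#' @name effect_sizes
NULL

#' @rdname effect_sizes
#' @export
phi_coefficient <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  margins <- c(rowSums(counts), colSums(counts))
  if (any(margins == 0)) {
    warning("phi undefined: zero margin in 2x2 table", call. = FALSE)
    return(NA_real_)
  }
  (counts[1, 1] * counts[2, 2] - counts[1, 2] * counts[2, 1]) /
    sqrt(prod(margins))
}

#' @rdname effect_sizes
#' @export
cramers_v <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    warning("Cramer's V undefined: zero margin", call. = FALSE)
    return(NA_real_)
  }
  chi2 <- suppressWarnings(
    stats::chisq.test(counts, correct = FALSE)$statistic
  )
  unname(sqrt(chi2 / (sum(counts) * (min(dim(counts)) - 1))))
}

#' @rdname effect_sizes
#' @export
eta_coefficient <- function(groups, values) {
  stopifnot(length(groups) == length(values), !anyNA(values))
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  if (ss_total == 0) {
    warning("eta undefined: metric variable is constant", call. = FALSE)
    return(NA_real_)
  }
  group_means <- tapply(values, groups, mean)
  group_n <- tapply(values, groups, length)
  ss_between <- sum(group_n * (group_means - grand)^2)
  sqrt(ss_between / ss_total)
}

#' Pre/post comparison of one variable
#'
#' Runs the Mann-Whitney U test between the pre- and post-period values
#' of a variable (categorical levels are rank-tested on their integer
#' coding, as is customary for ordinal claims-table comparisons) and
#' pairs it with the scale-appropriate effect size: phi for binary
#' variables, Cramer's V for nominal variables with three or more
#' levels, eta for metric variables.
#'
#' @param pre,post Vectors of the variable in each period (factor,
#'   character, logical or numeric).
#' @param variable Name used in the output row.
#' @param type `"binary"`, `"nominal"` or `"metric"`; the default
#'   `"auto"` infers it from the data.
#' @return One-row tibble: `variable`, `test`, `p_value`, `effect`,
#'   `effect_value`, `n_pre`, `n_post`.
#' @export
compare_groups <- function(pre, post, variable = "variable",
                           type = c("auto", "binary", "nominal", "metric")) {
  type <- match.arg(type)
  if (type == "auto") {
    if (is.logical(pre) ||
        (!is.numeric(pre) && length(unique(c(pre, post))) <= 2L)) {
      type <- "binary"
    } else if (is.numeric(pre) && !is.factor(pre)) {
      type <- "metric"
    } else {
      type <- "nominal"
    }
  }
  if (is.numeric(pre) && type == "metric") {
    xs <- as.numeric(pre)
    ys <- as.numeric(post)
  } else {
    lev <- if (is.factor(pre)) levels(pre) else sort(unique(c(as.character(pre),
                                                              as.character(post))))
    xs <- as.integer(factor(as.character(pre), levels = lev))
    ys <- as.integer(factor(as.character(post), levels = lev))
  }
  mwu <- mann_whitney_u(xs, ys)
  effect_value <- switch(
    type,
    binary = {
      lev <- sort(unique(c(xs, ys)))
      tab <- rbind(pre = table(factor(xs, levels = lev)),
                   post = table(factor(ys, levels = lev)))
      phi_coefficient(tab)
    },
    nominal = {
      lev <- sort(unique(c(xs, ys)))
      tab <- rbind(pre = table(factor(xs, levels = lev)),
                   post = table(factor(ys, levels = lev)))
      cramers_v(tab)
    },
    metric = eta_coefficient(
      rep(c("pre", "post"), c(length(xs), length(ys))), c(xs, ys)
    )
  )
  tibble::tibble(
    variable = variable,
    test = "mann_whitney",
    p_value = mwu$p_value,
    effect = switch(type, binary = "phi", nominal = "cramers_v", metric = "eta"),
    effect_value = effect_value,
    n_pre = length(xs),
    n_post = length(ys)
  )
}
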