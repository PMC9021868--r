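# Method agreement: Bland-Altman pairwise difference analysis between the
# chilling-requirement estimates of different break-date methods.

#' Bland-Altman agreement analysis
#'
#' For paired per-cultivar estimates from two methods, computes the
#' differences `d_i = a_i - b_i` and means `(a_i + b_i) / 2`, the mean
#' difference (bias), the 95 percent limits of agreement
#' `mean(d) +/- 1.96 * sd(d)` (sample SD, fixed normal multiplier), and the
#' fraction of pairs falling inside the limits (points exactly on a limit
#' count as inside). The two methods are declared in agreement when at
#' least 95 percent of pairs fall within the limits.
#'
#' @param values_a,values_b Equal-length numeric vectors (>= 3 pairs), e.g.
#'   chill portions per cultivar from two methods.
#' @param pair Optional character pair of method names for labelling.
#' @return An object of class `bland_altman`: list with `pair`, `n`,
#'   `mean_diff`, `sd_diff`, `loa` (lower, upper), `inside_fraction`,
#'   `agree`, and the per-pair `differences` and `means`.
#' @export
bland_altman <- function(values_a, values_b, pair = c("A", "B")) {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) != length(values_b)) stop("paired vectors must have equal length")
  if (length(values_a) < 3) stop("need at least 3 pairs")
  d <- values_a - values_b
  m <- (values_a + values_b) / 2
  md <- mean(d)
  sdd <- sd(d)
  loa <- c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd)
  inside <- mean(d >= loa[["lower"]] & d <= loa[["upper"]])
  structure(
    list(pair = pair, n = length(d), mean_diff = md, sd_diff = sdd,
         loa = loa, inside_fraction = inside, agree = inside >= 0.95,
         differences = d, means = m),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman %s vs %s: bias %.2f, LoA [%.2f, %.2f], %.0f%% inside, %s>\n",
    x$pair[1], x$pair[2], x$mean_diff, x$loa[["lower"]], x$loa[["upper"]],
    100 * x$inside_fraction, if (x$agree) "agree" else "disagree"))
  invisible(x)
}

#' Column summary: min, max, mean
#'
#' Range and mean of a per-cultivar requirement column, as used to report
#' the spread of each method over the cultivar set.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `min`, `max`, `mean`.
#' @export
column_summary <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input")
  c(min = min(values), max = max(values), mean = mean(values))
}

#' All pairwise Bland-Altman comparisons
#'
#' Enumerates every unordered pair of method columns and runs
#' [bland_altman()] on each.
#'
#' @param estimates Data frame or matrix with one row per cultivar and one
#'   column per method (column names are method names).
#' @return A data frame `pair`, `mean_diff`, `loa_low`, `loa_high`,
#'   `inside_fraction`, `agree`, with the `bland_altman` objects attached as
#'   attribute `reports`.
#' @export
compare_methods <- function(estimates) {
  estimates <- as.data.frame(estimates)
  methods <- names(estimates)
  if (length(methods) < 2) stop("need at least two method columns")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  reports <- lapply(pairs, function(p) {
    bland_altman(estimates[[p[1]]], estimates[[p[2]]], pair = p)
  })
  out <- data.frame(
    pair = vapply(reports, function(r) paste(r$pair, collapse = " vs "), character(1)),
    mean_diff = vapply(reports, `[[`, numeric(1), "mean_diff"),
    loa_low = vapply(reports, function(r) r$loa[["lower"]], numeric(1)),
    loa_high = vapply(reports, function(r) r$loa[["upper"]], numeric(1)),
    inside_fraction = vapply(reports, `[[`, numeric(1), "inside_fraction"),
    agree = vapply(reports, `[[`, logical(1), "agree")
  )
  attr(out, "reports") <- reports
  out
}
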