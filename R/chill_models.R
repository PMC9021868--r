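# Chill and heat accumulation models on hourly temperature series.
#
# All models take a temperature_series and return a chill_series: a data
# frame `timestamp`, `contribution`, `cumulative` with attributes `model`
# and `start_date`. `cumulative` is the running total at the END of each
# hour; the conceptual value at the accumulation start is 0.

#' Canonical constants of the two-step dynamic chill model
#'
#' The published formulation of the dynamic model in Kelvin: `slp` and
#' `tetmlt` shape the logistic conversion fraction, `e0`/`e1` are activation
#' energies and `a0`/`a1` pre-exponential factors of the formation and
#' destruction steps, `crit` is the intermediate-pool level at which
#' conversion to a chill portion fires, and `kelvin_offset` the Celsius
#' to Kelvin offset used by the canonical transcription (273, not 273.15).
#' Frozen here for bit-reproducibility across installs.
#'
#' @return Named list of model constants.
#' @export
dynamic_params <- function() {
  list(slp = 1.6, tetmlt = 277, e0 = 4153.5, e1 = 12888.8,
       a0 = 1.395e5, a1 = 2.567e18, crit = 1, kelvin_offset = 273)
}

# Utah stepwise weight table (full canonical table; the positive band
# 1.5-12.4 degC is the one usually quoted, but the negative bands above
# 15.9 degC are required by the Utah start-date rule).
#   (-Inf,1.4]:0  (1.4,2.4]:0.5  (2.4,9.1]:1  (9.1,12.4]:0.5
#   (12.4,15.9]:0  (15.9,18]:-0.5  (18,Inf):-1
utah_weight <- function(temp_c) {
  w <- numeric(length(temp_c))
  w[temp_c > 1.4 & temp_c <= 2.4] <- 0.5
  w[temp_c > 2.4 & temp_c <= 9.1] <- 1
  w[temp_c > 9.1 & temp_c <= 12.4] <- 0.5
  w[temp_c > 15.9 & temp_c <= 18] <- -0.5
  w[temp_c > 18] <- -1
  w
}

new_chill_series <- function(series, contribution, model, start_date) {
  x <- data.frame(timestamp = series$timestamp,
                  contribution = contribution,
                  cumulative = cumsum(contribution))
  attr(x, "model") <- model
  attr(x, "start_date") <- start_date
  class(x) <- c("chill_series", "data.frame")
  x
}

#' @export
print.chill_series <- function(x, ...) {
  cat(sprintf("<chill_series %s: %d h from %s, total %.3f>\n",
              attr(x, "model"), nrow(x),
              format(attr(x, "start_date")),
              if (nrow(x)) x$cumulative[nrow(x)] else 0))
  invisible(x)
}

#' Dynamic model chill portions (CP)
#'
#' Two-step hourly recursion: cold hours build an intermediate product that
#' relaxes toward a temperature-dependent equilibrium at a
#' temperature-dependent rate; warm hours can deplete this pool. Whenever
#' the pool reaches the critical level (1), a temperature-dependent fraction
#' converts irreversibly into chill portions — portions, once formed, cannot
#' be destroyed, so the cumulative CP curve is non-decreasing.
#'
#' @param series A [temperature_series()] at hourly spacing.
#' @param params Model constants, see [dynamic_params()].
#' @param state Initial intermediate-pool level; carrying the `final_state`
#'   attribute of a previous chunk makes accumulation invariant to splitting
#'   a series into consecutive chunks.
#' @return A `chill_series` (model `"dynamic_CP"`) with attribute
#'   `final_state`.
#' @export
dynamic_chill_portions <- function(series, params = dynamic_params(),
                                   state = 0) {
  validate_temperature_series(series, allow_gaps = FALSE)
  if (nrow(series) == 0) {
    out <- new_chill_series(series, numeric(0), "dynamic_CP", NA)
    attr(out, "final_state") <- state
    return(out)
  }
  res <- dynamic_portions_cpp(series$temp_c, params$slp, params$tetmlt,
                              params$e0, params$e1, params$a0, params$a1,
                              params$crit, params$kelvin_offset, state)
  out <- new_chill_series(series, res$delta, "dynamic_CP",
                          as.Date(series$timestamp[1], tz = "UTC"))
  attr(out, "final_state") <- res$state
  out
}

#' Utah model chill units (CU)
#'
#' Each hour contributes a stepwise weight of its temperature: full weight
#' between 2.5 and 9.1 degC, half weight on the shoulders (1.5-2.4 and
#' 9.2-12.4 degC), zero between 12.5 and 15.9 degC, and negative weights
#' above (-0.5 up to 18 degC, -1 beyond), so warm spells subtract units and
#' the cumulative CU curve may decrease.
#'
#' @param series A [temperature_series()] at hourly spacing.
#' @return A `chill_series` (model `"utah_CU"`).
#' @export
utah_chill_units <- function(series) {
  validate_temperature_series(series, allow_gaps = FALSE)
  new_chill_series(series, utah_weight(series$temp_c), "utah_CU",
                   if (nrow(series)) as.Date(series$timestamp[1], tz = "UTC") else NA)
}

#' Utah accumulation start: the day of maximum negative effect
#'
#' The Utah chilling requirement is counted from the day on which the
#' running cumulative CU reaches its minimum (the day when warm autumn
#' temperatures produced the maximum negative effect); accumulation restarts
#' at zero from the following hour. Ties are broken by the latest such day;
#' if the cumulative never goes negative the series start is returned.
#'
#' @param series A `chill_series` produced by [utah_chill_units()]
#'   (conventionally computed from September 1).
#' @return A list: `start_date` (the day of the minimum), `restart_index`
#'   (first hour counted after the restart) and `series`, a new
#'   `chill_series` re-accumulated from that hour.
#' @export
utah_start_date <- function(series) {
  stopifnot(inherits(series, "chill_series"),
            identical(attr(series, "model"), "utah_CU"))
  cum0 <- c(0, series$cumulative)            # state before any hour is 0
  i <- max(which(cum0 == min(cum0)))         # latest minimum
  if (i == 1L) {
    return(list(start_date = attr(series, "start_date"),
                restart_index = 1L, series = series))
  }
  start_date <- as.Date(series$timestamp[i - 1L], tz = "UTC")
  # re-accumulate from the following hour
  keep <- seq.int(i, nrow(series))
  contr <- series$contribution[keep]
  out <- data.frame(timestamp = series$timestamp[keep], contribution = contr,
                    cumulative = cumsum(contr))
  attr(out, "model") <- "utah_CU"
  attr(out, "start_date") <- start_date
  class(out) <- c("chill_series", "data.frame")
  list(start_date = start_date, restart_index = i, series = out)
}

#' Weinberger chilling hours (CH)
#'
#' One chilling hour per hour strictly below 7.2 degC (45 F). The
#' accumulation start is the first qualifying hour in autumn.
#'
#' @param series A [temperature_series()] at hourly spacing.
#' @return A `chill_series` (model `"weinberger_CH"`); `start_date` is the
#'   date of the first sub-7.2 degC hour (`NA` if none).
#' @export
weinberger_chill_hours <- function(series) {
  validate_temperature_series(series, allow_gaps = FALSE)
  contr <- as.numeric(series$temp_c < 7.2)
  first <- which(contr > 0)[1]
  start <- if (is.na(first)) as.Date(NA) else
    as.Date(series$timestamp[first], tz = "UTC")
  new_chill_series(series, contr, "weinberger_CH", start)
}

#' Growing degree hours (GDH)
#'
#' Linear heat accumulation above a 4.5 degC base with a 25 degC cap: each
#' hour contributes `max(0, min(T, 25) - 4.5)` degree-hours. Used to time
#' bloom after endodormancy release.
#'
#' @param series A [temperature_series()] at hourly spacing, conventionally
#'   starting at the endodormancy-break date.
#' @param base,cap Base and cap temperatures in degC.
#' @return A `chill_series` (model `"gdh_GDH"`).
#' @export
growing_degree_hours <- function(series, base = 4.5, cap = 25) {
  validate_temperature_series(series, allow_gaps = FALSE)
  contr <- pmax(0, pmin(series$temp_c, cap) - base)
  new_chill_series(series, contr, "gdh_GDH",
                   if (nrow(series)) as.Date(series$timestamp[1], tz = "UTC") else NA)
}
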