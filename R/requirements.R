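# Requirements pipeline: chill accumulated from the model-specific start to
# the endodormancy-break date (chilling requirement, CR) and heat
# accumulated from the break to full bloom (heat requirement, HR), with
# per-cultivar summaries and band classification.

#' Chilling requirement to a break date
#'
#' Accumulates the chosen chill model over one dormancy season from its
#' model-specific start to 24:00 of the break date: the Dynamic model
#' accumulates from September 1 (the season start); the Utah model restarts
#' at the day of maximum negative effect ([utah_start_date()]); the
#' Weinberger model counts from the first sub-7.2 degC hour in autumn.
#'
#' @param weather A [temperature_series()] covering the season.
#' @param season A [season()] object.
#' @param break_date Endodormancy-break `Date` within the season.
#' @param model `"dynamic"`, `"utah"` or `"weinberger"`.
#' @param params Dynamic-model constants, see [dynamic_params()].
#' @return The accumulated CP, CU or CH at the end of the break date. A
#'   break date preceding the accumulation start returns 0 with a warning.
#' @export
chilling_requirement <- function(weather, season, break_date,
                                 model = c("dynamic", "utah", "weinberger"),
                                 params = dynamic_params()) {
  model <- match.arg(model)
  break_date <- as.Date(break_date)
  stopifnot(inherits(season, "season"))
  if (break_date < season$start || break_date > season$end) {
    stop("break_date outside season ", season$label)
  }
  ser <- season_slice(weather, season)
  cs <- switch(model,
               dynamic = dynamic_chill_portions(ser, params),
               utah = utah_start_date(utah_chill_units(ser))$series,
               weinberger = weinberger_chill_hours(ser))
  start <- attr(cs, "start_date")
  if (!is.na(start) && break_date < start) {
    warning("break date ", format(break_date),
            " precedes accumulation start ", format(start), "; returning 0")
    return(0)
  }
  cutoff <- as.POSIXct(paste(break_date + 1, "00:00:00"), tz = "UTC")
  idx <- which(cs$timestamp < cutoff)
  if (!length(idx)) return(0)
  cs$cumulative[max(idx)]
}

#' Heat requirement from break to bloom
#'
#' Growing degree hours accumulated over the closed day span from 00:00 of
#' the break date to 24:00 of the F50 full-bloom date.
#'
#' @param weather A [temperature_series()] covering the span.
#' @param break_date Endodormancy-break `Date`.
#' @param f50_date Full-bloom `Date` (must not precede the break).
#' @param base,cap GDH base and cap temperatures (degC).
#' @return Accumulated GDH.
#' @export
heat_requirement <- function(weather, break_date, f50_date,
                             base = 4.5, cap = 25) {
  break_date <- as.Date(break_date)
  f50_date <- as.Date(f50_date)
  if (f50_date < break_date) stop("f50_date precedes break_date")
  from <- as.POSIXct(paste(break_date, "00:00:00"), tz = "UTC")
  to <- as.POSIXct(paste(f50_date + 1, "00:00:00"), tz = "UTC")
  keep <- weather$timestamp >= from & weather$timestamp < to
  sub <- weather[keep, , drop = FALSE]
  expected <- as.numeric(to - from, units = "hours")
  if (nrow(sub) != expected) stop("weather does not cover the break-to-bloom span")
  class(sub) <- c("temperature_series", "data.frame")
  gs <- growing_degree_hours(sub, base = base, cap = cap)
  gs$cumulative[nrow(gs)]
}

#' Per-cultivar summary: mean, SD, coefficient of variation
#'
#' Sample statistics over per-season requirement values: mean, sample SD
#' (n - 1 denominator; a single season reports SD 0 with `single = TRUE`)
#' and the coefficient of variation `cv = 100 * sd / mean` in percent
#' (undefined, `NA`, when the mean is 0).
#'
#' @param values Numeric vector of per-season values (length >= 1).
#' @return A list: `mean`, `sd`, `cv`, `n`, `single`.
#' @export
summarize_cultivar <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 1, !anyNA(values))
  m <- mean(values)
  s <- if (length(values) == 1) 0 else sd(values)
  cv <- if (m == 0) NA_real_ else 100 * s / m
  list(mean = m, sd = s, cv = cv, n = length(values),
       single = length(values) == 1)
}

#' Classify a chilling requirement (chill portions)
#'
#' Bands: high >= 66 CP; medium 56 to <66 CP; low-medium 50 to <56 CP.
#' Values below 50 CP fall outside the established bands and are flagged
#' `"below_range"` rather than silently binned.
#'
#' @param value Chilling requirement in CP (>= 0); vectorised.
#' @return Character vector: `"high"`, `"medium"`, `"low_medium"` or
#'   `"below_range"`.
#' @export
classify_cr <- function(value) {
  stopifnot(all(value >= 0))
  ifelse(value >= 66, "high",
         ifelse(value >= 56, "medium",
                ifelse(value >= 50, "low_medium", "below_range")))
}

#' Classify a heat requirement (growing degree hours)
#'
#' Bands: high >= 4101 GDH; medium above 3900 and below 4101 GDH; low
#' <= 3900 GDH. The real-valued gap between the printed integer bounds
#' (3900, 3901) is closed upward into the medium band.
#'
#' @param value Heat requirement in GDH (>= 0); vectorised.
#' @return Character vector: `"high"`, `"medium"` or `"low"`.
#' @export
classify_hr <- function(value) {
  stopifnot(all(value >= 0))
  ifelse(value >= 4101, "high", ifelse(value > 3900, "medium", "low"))
}

#' Requirements summary for one cultivar and one break-date method
#'
#' Computes the chilling requirement (per chill model) and the heat
#' requirement of a cultivar, given its break dates. Experimental and
#' biomarker methods provide one break date per season: CR/HR are computed
#' per season and averaged. Statistical methods provide a single
#' day-of-season index: the same calendar day is applied in every season,
#' and SD/cv describe the spread of the accumulations to that fixed date
#' across seasons.
#'
#' @param weather_seasons Named list of per-season [temperature_series()].
#' @param blooms Data frame `season`, `f50_date` for the cultivar.
#' @param breaks Either a data frame `season`, `break_date` (per-season
#'   dates) or a single day-of-season index (statistical methods).
#' @param models Chill models to report (subset of
#'   `c("dynamic", "utah", "weinberger")`).
#' @return A list with one element per chill model (each a
#'   [summarize_cultivar()] list plus `class` for the dynamic model) and an
#'   `hr` element (summary plus `class`); also `break_day_index` or
#'   `per_season_breaks`.
#' @export
requirements_table <- function(weather_seasons, blooms, breaks,
                               models = c("dynamic", "utah", "weinberger")) {
  models <- match.arg(models, several.ok = TRUE)
  labs <- names(weather_seasons)
  if (is.data.frame(breaks)) {
    bd <- setNames(as.Date(breaks$break_date), breaks$season)
    labs <- intersect(labs, names(bd))
  } else {
    idx <- as.integer(breaks)
    bd <- setNames(as.Date(vapply(labs, function(sl)
      as.character(season_date(idx, season(sl))), character(1))), labs)
  }
  f50 <- setNames(as.Date(blooms$f50_date), blooms$season)
  labs <- intersect(labs, names(f50))
  if (!length(labs)) stop("no season with weather, break and bloom data")
  out <- list()
  for (m in models) {
    vals <- vapply(labs, function(sl) {
      chilling_requirement(weather_seasons[[sl]], season(sl), bd[[sl]], m)
    }, numeric(1))
    smry <- summarize_cultivar(vals)
    smry$per_season <- vals
    if (m == "dynamic") smry$class <- classify_cr(smry$mean)
    out[[m]] <- smry
  }
  hr_vals <- vapply(labs, function(sl) {
    heat_requirement(weather_seasons[[sl]], bd[[sl]], f50[[sl]])
  }, numeric(1))
  hr <- summarize_cultivar(hr_vals)
  hr$per_season <- hr_vals
  hr$class <- classify_hr(hr$mean)
  out$hr <- hr
  if (is.data.frame(breaks)) out$per_season_breaks <- bd[labs]
  else out$break_day_index <- as.integer(breaks)
  out
}
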