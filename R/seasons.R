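#' Dormancy season (September 1 to April 30)
#'
#' A dormancy season spans the autumn and winter bridging two calendar years:
#' by default September 1 of the first year through April 30 of the second.
#' Day-of-season indices follow the convention that October 1 is day 1 and
#' April 30 is day 212 in a season whose February has 28 days (213 when the
#' season contains a February 29; real days are never dropped).
#'
#' @param first_year Integer, the calendar year in which the season starts,
#'   or a label such as `"2016-2017"`.
#' @param start_month,start_day Season start (default September 1).
#' @param end_month,end_day Season end (default April 30 of the next year).
#' @return An object of class `season`: a list with `label`, `first_year`,
#'   `second_year`, `start` and `end` (`Date`).
#' @examples
#' s <- season(2016)
#' day_of_season(as.Date("2016-10-01"), s)  # 1
#' day_of_season(as.Date("2017-04-30"), s)  # 212
#' @export
season <- function(first_year, start_month = 9L, start_day = 1L,
                   end_month = 4L, end_day = 30L) {
  if (is.character(first_year)) {
    first_year <- as.integer(sub("[-/–].*$", "", first_year))
  }
  first_year <- as.integer(first_year)
  stopifnot(is.finite(first_year))
  start <- as.Date(sprintf("%04d-%02d-%02d", first_year, start_month, start_day))
  end <- as.Date(sprintf("%04d-%02d-%02d", first_year + 1L, end_month, end_day))
  if (end <= start) stop("season end must be after season start")
  structure(
    list(label = sprintf("%d-%d", first_year, first_year + 1L),
         first_year = first_year, second_year = first_year + 1L,
         start = start, end = end),
    class = "season"
  )
}

#' @export
print.season <- function(x, ...) {
  cat(sprintf("<season %s: %s .. %s>\n", x$label,
              format(x$start), format(x$end)))
  invisible(x)
}

#' Day-of-season index (October 1 = day 1)
#'
#' Maps calendar dates to the day-of-season grid used by the statistical
#' break-date estimators. October 1 of the season's first year is day 1;
#' April 30 is day 212 in a non-leap-February season and 213 otherwise.
#' September dates map to indices <= 0.
#'
#' @param dates A `Date` vector (or anything coercible by `as.Date()`).
#' @param season A [season()] object.
#' @return Integer vector of day indices.
#' @seealso [season_date()] for the inverse mapping.
#' @export
day_of_season <- function(dates, season) {
  stopifnot(inherits(season, "season"))
  oct1 <- as.Date(sprintf("%04d-10-01", season$first_year))
  as.integer(as.Date(dates) - oct1) + 1L
}

#' Calendar date of a day-of-season index
#'
#' @param index Integer day-of-season index (October 1 = 1).
#' @param season A [season()] object.
#' @return A `Date` vector.
#' @export
season_date <- function(index, season) {
  stopifnot(inherits(season, "season"))
  oct1 <- as.Date(sprintf("%04d-10-01", season$first_year))
  oct1 + (as.integer(round(index)) - 1L)
}

#' Seasons covered by a temperature record
#'
#' Lists the dormancy seasons fully contained in a temperature series.
#'
#' @param series A temperature series (see [read_temperature()]).
#' @inheritParams season
#' @return A list of [season()] objects.
#' @export
seasons_covered <- function(series, start_month = 9L, start_day = 1L,
                            end_month = 4L, end_day = 30L) {
  stopifnot(is.data.frame(series))
  rng <- range(series$timestamp)
  years <- seq.int(as.integer(format(rng[1], "%Y")) - 1L,
                   as.integer(format(rng[2], "%Y")))
  out <- list()
  for (y in years) {
    s <- season(y, start_month, start_day, end_month, end_day)
    first <- as.POSIXct(paste(s$start, "00:00:00"), tz = "UTC")
    last <- as.POSIXct(paste(s$end, "23:00:00"), tz = "UTC")
    if (rng[1] <= first && rng[2] >= last) out[[s$label]] <- s
  }
  out
}

# round-half-up to integer; used wherever mid-point / mean dates are reported
round_half_up <- function(x) floor(x + 0.5)
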