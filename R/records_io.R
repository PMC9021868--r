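#' Build and validate an hourly temperature series
#'
#' The temperature series is the substrate of every accumulation model: a
#' data frame with a strictly increasing hourly `timestamp` column (POSIXct,
#' treated as local standard time, stored as UTC, no DST shifts) and an air
#' temperature column `temp_c` in degrees Celsius.
#'
#' @param timestamps POSIXct vector at hourly resolution.
#' @param temp_c Numeric vector, air temperature in Celsius.
#' @param allow_gaps If `FALSE` (default) timestamps must be contiguous at
#'   exactly one hour spacing.
#' @return A `temperature_series` data frame with columns `timestamp`,
#'   `temp_c`.
#' @export
temperature_series <- function(timestamps, temp_c, allow_gaps = FALSE) {
  if (length(timestamps) != length(temp_c)) {
    stop("timestamps and temp_c must have equal length")
  }
  timestamps <- .POSIXct(as.numeric(as.POSIXct(timestamps, tz = "UTC")),
                         tz = "UTC")
  temp_c <- as.numeric(temp_c)
  x <- data.frame(timestamp = timestamps, temp_c = temp_c)
  class(x) <- c("temperature_series", "data.frame")
  validate_temperature_series(x, allow_gaps = allow_gaps)
  x
}

#' @rdname temperature_series
#' @param x A temperature series.
#' @export
validate_temperature_series <- function(x, allow_gaps = FALSE) {
  stopifnot(is.data.frame(x), all(c("timestamp", "temp_c") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$temp_c)) stop("temp_c contains missing values")
  if (any(x$temp_c < -50 | x$temp_c > 60)) {
    stop("temp_c outside plausible range [-50, 60] degC")
  }
  d <- diff(as.numeric(x$timestamp)) / 3600
  if (any(d <= 0)) stop("timestamps must be strictly increasing")
  if (any(abs(d - round(d)) > 1e-6)) stop("timestamps must fall on whole hours")
  if (!allow_gaps && any(round(d) != 1)) {
    stop("timestamps must be contiguous at 1-hour spacing (gap detected)")
  }
  invisible(x)
}

#' Read an hourly temperature record from CSV
#'
#' Expects columns `timestamp` (ISO-8601, e.g. `2016-11-01T13:00:00` or
#' `2016-11-01 13:00:00`) and `temp_c`. Timestamps are interpreted as local
#' standard time (no DST); duplicate or missing DST hours must be cleaned
#' beforehand or they trigger the gap policy.
#'
#' @param path Path to the CSV file.
#' @param fill_policy `"error"` rejects any gap; `"linear_fill_max6h"`
#'   linearly interpolates gaps of at most 6 hours and rejects longer ones.
#' @return A [temperature_series()].
#' @export
read_temperature <- function(path, fill_policy = c("error", "linear_fill_max6h")) {
  fill_policy <- match.arg(fill_policy)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(raw))) {
    stop("temperature CSV must have columns 'timestamp' and 'temp_c'")
  }
  ts <- parse_iso_hour(raw$timestamp)
  if (anyNA(ts)) stop("malformed timestamp row(s): ",
                      paste(utils::head(raw$timestamp[is.na(ts)], 3), collapse = ", "))
  tc <- suppressWarnings(as.numeric(raw$temp_c))
  if (anyNA(tc)) stop("malformed temp_c row(s)")
  d <- diff(as.numeric(ts)) / 3600
  if (any(d <= 0)) stop("timestamps must be strictly increasing")
  gaps <- which(round(d) > 1)
  if (length(gaps)) {
    if (fill_policy == "error") {
      stop("gap of ", max(d[gaps]), " h at ", format(ts[gaps[1]]),
           "; use fill_policy = 'linear_fill_max6h' or clean the record")
    }
    if (any(d[gaps] > 6)) {
      stop("gap of ", max(d[gaps]), " h exceeds the 6-hour fill limit")
    }
    full <- seq(ts[1], ts[length(ts)], by = 3600)
    tc <- approx(as.numeric(ts), tc, xout = as.numeric(full))$y
    ts <- full
  }
  temperature_series(ts, tc)
}

parse_iso_hour <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"), tz = "UTC")
  retry <- is.na(out)
  if (any(retry)) {
    out[retry] <- as.POSIXct(strptime(x[retry], "%Y-%m-%d %H:%M", tz = "UTC"),
                             tz = "UTC")
  }
  out
}

#' Write an hourly temperature record to CSV
#'
#' Values are written with full double precision so that
#' `read_temperature(write_temperature(x))` reproduces `x` bit-exactly.
#'
#' @param series A [temperature_series()].
#' @param path Output path.
#' @export
write_temperature <- function(series, path) {
  validate_temperature_series(series, allow_gaps = TRUE)
  out <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temp_c = formatC(series$temp_c, digits = 17, format = "g"),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read full-bloom (F50) records
#'
#' CSV columns: `cultivar`, `season` (e.g. `"2016-2017"`), `f50_date`
#' (ISO date of 50 percent open flowers). One record per cultivar x season.
#'
#' @param path Path to the CSV file.
#' @return A data frame `cultivar`, `season`, `f50_date` (`Date`).
#' @export
read_bloom_records <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "season", "f50_date")
  if (!all(need %in% names(raw))) {
    stop("bloom CSV must have columns ", paste(need, collapse = ", "))
  }
  raw$f50_date <- as.Date(raw$f50_date)
  if (anyNA(raw$f50_date)) stop("malformed f50_date row(s)")
  if (anyDuplicated(raw[c("cultivar", "season")])) {
    stop("duplicate cultivar x season bloom record")
  }
  raw[need]
}

#' Read flower-bud weight trials (forcing test)
#'
#' Long-format CSV: `cultivar`, `collection_date`, `context`
#' (`field` or `chamber`), `weight_mg`. Each collection date carries the
#' weights of buds sampled in the field on day 0 and of buds weighed after
#' the fixed 8-day stay in the forcing chamber.
#'
#' @param path Path to the CSV file.
#' @return A data frame with the four columns above (`collection_date` as
#'   `Date`, `context` as character).
#' @export
read_bud_weight_trials <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "collection_date", "context", "weight_mg")
  if (!all(need %in% names(raw))) {
    stop("bud-weight CSV must have columns ", paste(need, collapse = ", "))
  }
  raw$collection_date <- as.Date(raw$collection_date)
  if (anyNA(raw$collection_date)) stop("malformed collection_date row(s)")
  if (!all(raw$context %in% c("field", "chamber"))) {
    stop("context must be 'field' or 'chamber'")
  }
  raw$weight_mg <- as.numeric(raw$weight_mg)
  if (anyNA(raw$weight_mg) || any(raw$weight_mg <= 0)) {
    stop("weight_mg must be positive")
  }
  raw[need]
}

#' Read externally observed biomarker break dates
#'
#' CSV columns: `cultivar`, `season`, `break_date` — e.g. the first observed
#' date of male-meiosis onset (callose wall around microspore mother cells).
#'
#' @param path Path to the CSV file.
#' @return A data frame `cultivar`, `season`, `break_date` (`Date`).
#' @export
read_biomarker_dates <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "season", "break_date")
  if (!all(need %in% names(raw))) {
    stop("biomarker CSV must have columns ", paste(need, collapse = ", "))
  }
  raw$break_date <- as.Date(raw$break_date)
  if (anyNA(raw$break_date)) stop("malformed break_date row(s)")
  raw[need]
}

#' Hourly temperatures from daily minima and maxima
#'
#' For users whose station provides only daily extremes. The documented
#' curve: the daily minimum is placed at 05:00 and the maximum at 14:00;
#' between them temperature follows a quarter-sine rise
#' `Tmin + (Tmax - Tmin) * sin(pi/2 * (h - 5) / 9)`; from 14:00 the
#' temperature decays linearly to the next day's 05:00 minimum. Hours before
#' 05:00 on the first day are held at that day's minimum; after 14:00 on the
#' last day the decay targets the same day's minimum. Daily extremes are
#' reproduced exactly at the anchor hours; a day's printed extremes can be
#' exceeded in its pre-dawn hours only when the previous day was much warmer
#' or colder (the cross-midnight decay carries the neighbouring day's value).
#'
#' @param daily Data frame with columns `date`, `tmin_c`, `tmax_c`.
#' @param method Interpolation curve; only `"sine_linear"` is implemented.
#' @return A [temperature_series()] with 24 values per day.
#' @export
interpolate_hourly <- function(daily, method = "sine_linear") {
  method <- match.arg(method, "sine_linear")
  stopifnot(is.data.frame(daily),
            all(c("date", "tmin_c", "tmax_c") %in% names(daily)))
  dts <- as.Date(daily$date)
  tmin <- as.numeric(daily$tmin_c)
  tmax <- as.numeric(daily$tmax_c)
  if (any(tmin > tmax)) stop("tmin_c > tmax_c on at least one day")
  if (any(diff(dts) != 1)) stop("daily records must be consecutive dates")
  n <- length(dts)
  temp <- numeric(24L * n)
  h_min <- 5L; h_max <- 14L
  for (d in seq_len(n)) {
    hrs <- 0:23
    v <- numeric(24)
    # pre-dawn: tail of yesterday's decay toward today's minimum
    pre <- hrs < h_min
    if (d == 1L) {
      v[pre] <- tmin[d]
    } else {
      elapsed <- (24L - h_max) + hrs[pre]          # hours since yesterday 14:00
      span <- 24L - h_max + h_min                  # 15-hour decay
      v[pre] <- tmax[d - 1L] + (tmin[d] - tmax[d - 1L]) * elapsed / span
    }
    rise <- hrs >= h_min & hrs <= h_max
    v[rise] <- tmin[d] +
      (tmax[d] - tmin[d]) * sin(pi / 2 * (hrs[rise] - h_min) / (h_max - h_min))
    post <- hrs > h_max
    target <- if (d == n) tmin[d] else tmin[d + 1L]
    span <- 24L - h_max + h_min
    v[post] <- tmax[d] + (target - tmax[d]) * (hrs[post] - h_max) / span
    temp[(d - 1L) * 24L + 1:24] <- v
  }
  ts0 <- as.POSIXct(paste(dts[1], "00:00:00"), tz = "UTC")
  temperature_series(seq(ts0, by = 3600, length.out = 24L * n), temp)
}

#' Daily mean temperature
#'
#' Arithmetic mean of the 24 hourly values of each complete calendar day.
#' Partial days at the series boundaries are dropped with a warning.
#'
#' @param series A [temperature_series()].
#' @return Data frame `date`, `tmean`.
#' @export
daily_mean <- function(series) {
  validate_temperature_series(series, allow_gaps = TRUE)
  day <- as.Date(format(series$timestamp, "%Y-%m-%d", tz = "UTC"))
  cnt <- table(day)
  partial <- names(cnt)[cnt < 24L]
  if (length(partial)) {
    warning("dropping ", length(partial), " partial day(s) at the boundaries")
  }
  keep <- !(as.character(day) %in% partial)
  agg <- aggregate(series$temp_c[keep], by = list(date = day[keep]), FUN = mean)
  names(agg)[2] <- "tmean"
  agg
}

#' Slice a temperature series to one dormancy season
#'
#' @param series A [temperature_series()].
#' @param season A [season()] object; the series must cover it entirely
#'   (September 1 00:00 through April 30 23:00 by default).
#' @return A [temperature_series()] restricted to the season.
#' @export
season_slice <- function(series, season) {
  stopifnot(inherits(season, "season"))
  validate_temperature_series(series, allow_gaps = TRUE)
  first <- as.POSIXct(paste(season$start, "00:00:00"), tz = "UTC")
  last <- as.POSIXct(paste(season$end, "23:00:00"), tz = "UTC")
  keep <- series$timestamp >= first & series$timestamp <= last
  out <- series[keep, , drop = FALSE]
  expected <- as.numeric(last - first, units = "hours") + 1
  if (nrow(out) != expected) {
    stop("series does not fully cover season ", season$label)
  }
  rownames(out) <- NULL
  class(out) <- c("temperature_series", "data.frame")
  out
}
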