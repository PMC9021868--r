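# Endodormancy-break estimators: forcing-test criterion, correlation
# sign-transition, and biomarker pass-through. The PLS route lives in pls.R.

#' Forcing-test break date (30 percent bud-weight criterion)
#'
#' Buds sampled in the field resume growth in a warm chamber only once
#' chilling is fulfilled. Trials are compared by the means of their 10-bud
#' samples: endodormancy is considered overcome at the first collection date
#' whose mean chamber weight after the 8-day stay is at least 1.30 times the
#' mean field weight (the 30 percent threshold is inclusive).
#'
#' @param trials Long-format data frame as from [read_bud_weight_trials()]
#'   (one cultivar, one season), columns `collection_date`, `context`
#'   (`field`/`chamber`), `weight_mg`.
#' @param threshold Relative weight increase defining release (default 0.30).
#' @return A list: `status` (`"released"` or `"not_released"`), `date` (the
#'   first qualifying collection date, `NA` if none) and `ratios`, the
#'   chamber/field mean weight ratio per collection date.
#' @export
forcing_break_date <- function(trials, threshold = 0.30) {
  stopifnot(all(c("collection_date", "context", "weight_mg") %in% names(trials)))
  dts <- sort(unique(as.Date(trials$collection_date)))
  ratio <- vapply(dts, function(d) {
    sub <- trials[as.Date(trials$collection_date) == d, ]
    fw <- sub$weight_mg[sub$context == "field"]
    cw <- sub$weight_mg[sub$context == "chamber"]
    if (!length(fw) || !length(cw)) {
      stop("collection ", format(d), " lacks field or chamber weights")
    }
    mean(cw) / mean(fw)
  }, numeric(1))
  hit <- which(ratio >= 1 + threshold)[1]
  if (is.na(hit)) {
    list(status = "not_released", date = as.Date(NA),
         ratios = setNames(ratio, format(dts)))
  } else {
    list(status = "released", date = dts[hit],
         ratios = setNames(ratio, format(dts)))
  }
}

#' Critical Pearson correlation coefficient
#'
#' Two-sided significance threshold for a Pearson correlation over
#' `n_years` paired observations: `r* = t / sqrt(t^2 + df)` with
#' `df = n_years - 2` and `t` the `1 - alpha/2` Student-t quantile. With 13
#' years at alpha 0.05 this is 0.553 (printed to 3 decimals).
#'
#' @param n_years Number of seasons in the correlation (>= 3).
#' @param alpha Two-sided significance level.
#' @return The critical correlation (full precision; round to 3 decimals for
#'   reporting).
#' @export
critical_pcc <- function(n_years, alpha = 0.05) {
  if (n_years < 3) stop("need at least 3 years for a correlation threshold")
  df <- n_years - 2
  t <- qt(1 - alpha / 2, df)
  t / sqrt(t^2 + df)
}

#' Moving-window temperature-bloom correlation profile
#'
#' For each day of the season grid (October 1 = day 1 through April 30), the
#' mean daily temperature is averaged over a centred window (default 15
#' days, truncated at the grid edges) and correlated across seasons with the
#' bloom day-of-season. Warm weather during chilling delays chill fulfilment
#' and hence bloom (positive correlation); warm weather during forcing
#' accelerates bloom (negative correlation); the sign transition brackets
#' the endodormancy-to-ecodormancy break.
#'
#' @param daily_means Data frame `season`, `date`, `tmean` covering each
#'   season's grid (see [daily_mean()]); seasons lacking bloom data are
#'   dropped with a warning.
#' @param blooms Data frame `season`, `f50_date` for one cultivar.
#' @param window_days Odd window length in days (default 15).
#' @param alpha Two-sided level for the significance threshold.
#' @param min_years Minimum number of usable seasons (default 11).
#' @return A `correlation_profile` data frame `day`, `pcc` with attributes
#'   `crit_r`, `n_seasons`, `seasons`, `zero_variance`.
#' @export
correlation_profile <- function(daily_means, blooms, window_days = 15,
                                alpha = 0.05, min_years = 11) {
  stopifnot(window_days %% 2 == 1, window_days >= 1)
  seasons <- intersect(unique(daily_means$season), unique(blooms$season))
  missing_bloom <- setdiff(unique(daily_means$season), unique(blooms$season))
  if (length(missing_bloom)) {
    warning("dropping season(s) without bloom record: ",
            paste(missing_bloom, collapse = ", "))
  }
  if (length(seasons) < min_years) {
    stop("need >= ", min_years, " seasons with both weather and bloom data; got ",
         length(seasons))
  }
  seasons <- sort(seasons)
  grids <- lapply(seasons, function(sl) {
    s <- season(sl)
    ndays <- as.integer(as.Date(sprintf("%04d-04-30", s$second_year)) -
                          as.Date(sprintf("%04d-10-01", s$first_year))) + 1L
    dm <- daily_means[daily_means$season == sl, ]
    idx <- day_of_season(dm$date, s)
    grid <- rep(NA_real_, ndays)
    keep <- idx >= 1 & idx <= ndays
    grid[idx[keep]] <- dm$tmean[keep]
    if (anyNA(grid)) stop("season ", sl, " does not cover the day grid")
    grid
  })
  ndays <- min(lengths(grids))                  # 212, or 213 in leap seasons
  half <- (window_days - 1) / 2
  wmeans <- vapply(grids, function(g) {
    vapply(seq_len(ndays), function(d) {
      mean(g[max(1, d - half):min(ndays, d + half)])
    }, numeric(1))
  }, numeric(ndays))                            # ndays x seasons
  bloom_doy <- vapply(seasons, function(sl) {
    as.numeric(day_of_season(blooms$f50_date[blooms$season == sl][1], season(sl)))
  }, numeric(1))
  zero_var <- sd(bloom_doy) == 0
  pcc <- if (zero_var) {
    rep(0, ndays)
  } else {
    p <- suppressWarnings(apply(wmeans, 1, cor, y = bloom_doy))
    p[is.na(p)] <- 0                            # zero-variance predictor days
    p
  }
  out <- data.frame(day = seq_len(ndays), pcc = pcc)
  attr(out, "crit_r") <- critical_pcc(length(seasons), alpha)
  attr(out, "n_seasons") <- length(seasons)
  attr(out, "seasons") <- seasons
  attr(out, "zero_variance") <- zero_var
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Break date from a correlation profile
#'
#' The transition period runs from `L`, the last day whose correlation is
#' significantly positive (`pcc >= +crit_r`), to `F`, the first day after
#' `L` significantly negative (`pcc <= -crit_r`). The break is the mid-point
#' `round((L + F) / 2)`, rounded half-up.
#'
#' @param profile A [correlation_profile()].
#' @return A list: `status` (`"ok"`/`"undetermined"`), `day_index` (the break
#'   on the day-of-season grid), `last_positive`, `first_negative`, and
#'   `diagnostic` when undetermined.
#' @export
correlation_break_date <- function(profile) {
  stopifnot(inherits(profile, "correlation_profile"))
  r <- attr(profile, "crit_r")
  pos <- which(profile$pcc >= r)
  if (!length(pos)) {
    return(list(status = "undetermined", day_index = NA_integer_,
                last_positive = NA_integer_, first_negative = NA_integer_,
                diagnostic = "no significantly positive day"))
  }
  L <- max(pos)
  neg <- which(profile$pcc <= -r & profile$day > L)
  if (!length(neg)) {
    return(list(status = "undetermined", day_index = NA_integer_,
                last_positive = L, first_negative = NA_integer_,
                diagnostic = "no significantly negative day after the last positive"))
  }
  F_ <- min(neg)
  list(status = "ok",
       day_index = as.integer(round_half_up((L + F_) / 2)),
       last_positive = as.integer(L), first_negative = as.integer(F_))
}

#' Biomarker break dates (pass-through)
#'
#' Externally observed endodormancy-break dates — e.g. the first microscopic
#' appearance of a callose wall around microspore mother cells at male
#' meiosis onset — are taken as-is, one per season, and summarised by their
#' mean. Dates are averaged on the day-of-season ordinal (October 1 = 1 of
#' each season) and rounded half-up.
#'
#' @param records Data frame `season`, `break_date` for one cultivar (see
#'   [read_biomarker_dates()]).
#' @return A list: `per_season` (named `Date` vector), `mean_day_index`
#'   (day-of-season ordinal of the mean) and `mean_date`, the mean mapped
#'   into the latest season's calendar.
#' @export
biomarker_break_dates <- function(records) {
  stopifnot(all(c("season", "break_date") %in% names(records)), nrow(records) >= 1)
  ord <- vapply(seq_len(nrow(records)), function(i) {
    as.numeric(day_of_season(records$break_date[i], season(records$season[i])))
  }, numeric(1))
  mean_idx <- round_half_up(mean(ord))
  last_season <- season(sort(records$season)[nrow(records)])
  list(per_season = setNames(as.Date(records$break_date), records$season),
       mean_day_index = as.integer(mean_idx),
       mean_date = season_date(mean_idx, last_season))
}
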