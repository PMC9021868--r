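# Synthetic multi-year weather and phenology generator. Emulates the data a
# long-term orchard study rests on: hourly station temperatures with
# seasonal, diurnal, autocorrelated-noise and interannual structure, and
# bloom dates produced by a sequential chill-then-heat ground truth
# (Dynamic CP to a cultivar-specific chilling requirement CR*, then GDH to
# a heat requirement HR*). Everything is seed-deterministic; per-season and
# per-cultivar RNG streams are derived from one master seed by fixed
# offsets, so adding cultivars never perturbs existing ones.

#' Configuration of the synthetic weather/phenology generator
#'
#' Defaults describe a dry inland Mediterranean climate of the kind the
#' long-term apricot records come from (Ebro valley): annual mean 15 degC
#' with a 9.5 degC seasonal half-range and the coldest day around
#' mid-January, a 5 degC diurnal half-range peaking at 14:00, synoptic
#' AR(1) noise at the daily time-step (coefficient 0.8 per day, innovation
#' SD 1.5 degC, hence a stationary SD of 2.5 degC and a decorrelation time
#' of about 4.5 days — the persistence of mid-latitude weather regimes),
#' and a 0.8 degC SD interannual mean shift. These
#' conditions yield season chill totals on the order of 90-110 CP by the
#' end of March, matching long-term records from such climates.
#'
#' @param n_seasons Number of dormancy seasons to simulate.
#' @param seed Master integer seed.
#' @param first_year Calendar year starting the first season.
#' @param annual_mean_c,annual_amplitude_c,coldest_doy Seasonal sinusoid:
#'   mean, half-range (degC) and day-of-year anchor of the coldest day.
#' @param diurnal_amplitude_c Diurnal half-range (degC), warmest at 14:00.
#' @param ar1,innovation_sd_c Daily-step AR(1) anomaly coefficient (in
#'   \[0, 1)) and innovation SD (degC); the anomaly is held constant within
#'   each day.
#' @param interannual_sd_c SD of the per-season mean temperature shift (degC).
#' @param cr_star True chilling requirement (Dynamic CP).
#' @param hr_star True heat requirement (GDH).
#' @param bloom_noise_days SD of the rounded Gaussian observation noise on
#'   the F50 date (days).
#' @param bud_ratio_noise SD of the noise on the chamber/field bud-weight
#'   ratio of synthetic forcing trials.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_seasons = 20, seed = 1, first_year = 2000,
                             annual_mean_c = 15, annual_amplitude_c = 9.5,
                             coldest_doy = 15, diurnal_amplitude_c = 5,
                             ar1 = 0.8, innovation_sd_c = 1.5,
                             interannual_sd_c = 0.8,
                             cr_star = 55, hr_star = 4100,
                             bloom_noise_days = 2, bud_ratio_noise = 0.05) {
  stopifnot(n_seasons >= 1, annual_amplitude_c >= 0, diurnal_amplitude_c >= 0,
            ar1 >= 0, ar1 < 1, innovation_sd_c >= 0, interannual_sd_c >= 0,
            cr_star >= 0, hr_star > 0, bloom_noise_days >= 0,
            bud_ratio_noise >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# derived RNG substream: exact in double arithmetic, always < 2^31 - 1
substream <- function(seed, i, j = 0) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 +
                i * 100003 + j * 7919) %% 2147483647)
}

#' Generate synthetic hourly weather
#'
#' One hourly [temperature_series()] per dormancy season (September 1 00:00
#' to April 30 23:00), built as seasonal sinusoid + per-season mean shift +
#' diurnal sinusoid + daily-step AR(1) anomaly (synoptic weather regimes,
#' constant within a day). Identical `config` and `stream` give
#' bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @param stream Integer stream offset (e.g. a cultivar/site index) keeping
#'   independent draws reproducibly separated.
#' @return Named list of [temperature_series()], one per season label.
#' @export
gen_weather <- function(config, stream = 0) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- list()
  for (k in seq_len(config$n_seasons)) {
    s <- season(config$first_year + k - 1L)
    ts0 <- as.POSIXct(paste(s$start, "00:00:00"), tz = "UTC")
    ts1 <- as.POSIXct(paste(s$end, "23:00:00"), tz = "UTC")
    tt <- seq(ts0, ts1, by = 3600)
    doy <- as.numeric(format(tt, "%j", tz = "UTC"))
    hour <- as.numeric(format(tt, "%H", tz = "UTC"))
    seasonal <- config$annual_mean_c -
      config$annual_amplitude_c * cos(2 * pi * (doy - config$coldest_doy) / 365.25)
    diurnal <- config$diurnal_amplitude_c * cos(2 * pi * (hour - 14) / 24)
    set.seed(substream(config$seed, k, 1000 * stream))
    shift <- rnorm(1, 0, config$interannual_sd_c)
    nday <- length(tt) / 24L
    noise <- if (config$innovation_sd_c > 0) {
      anom <- as.numeric(stats::filter(rnorm(nday, 0, config$innovation_sd_c),
                                       filter = config$ar1, method = "recursive"))
      rep(anom, each = 24L)
    } else rep(0, length(tt))
    out[[s$label]] <- temperature_series(tt, seasonal + shift + diurnal + noise)
  }
  out
}

#' Generate bloom records from a sequential chill-then-heat truth
#'
#' Per season, the true endodormancy break is the first hour at which
#' Dynamic chill portions (accumulated from September 1) reach `cr_star`;
#' the true F50 is the first hour thereafter at which growing degree hours
#' reach `hr_star`. The observed F50 adds rounded Gaussian day noise.
#' Seasons in which either requirement is unreachable are flagged
#' `no_bloom` (F50 `NA`).
#'
#' @param weather_seasons Named list of per-season [temperature_series()]
#'   (see [gen_weather()]).
#' @param config A [synthetic_config()].
#' @param stream Integer stream offset, as in [gen_weather()].
#' @param cultivar Cultivar name attached to the bloom records.
#' @return A list: `blooms` (data frame `cultivar`, `season`, `f50_date`;
#'   `no_bloom` seasons omitted) and `truth` (data frame `season`,
#'   `break_date`, `f50_true`, `no_bloom`).
#' @export
gen_bloom_records <- function(weather_seasons, config, stream = 0,
                              cultivar = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  labs <- names(weather_seasons)
  truth <- data.frame(season = labs, break_date = as.Date(NA),
                      f50_true = as.Date(NA), no_bloom = TRUE,
                      stringsAsFactors = FALSE)
  f50_obs <- rep(as.Date(NA), length(labs))
  for (k in seq_along(labs)) {
    ser <- weather_seasons[[k]]
    cp <- dynamic_chill_portions(ser)
    bi <- if (config$cr_star == 0) 1L else which(cp$cumulative >= config$cr_star)[1]
    if (is.na(bi)) next
    truth$break_date[k] <- as.Date(ser$timestamp[bi], tz = "UTC")
    if (bi >= nrow(ser)) next
    rest <- ser[seq.int(bi + 1L, nrow(ser)), , drop = FALSE]
    class(rest) <- c("temperature_series", "data.frame")
    gg <- growing_degree_hours(rest)
    fi <- which(gg$cumulative >= config$hr_star)[1]
    if (is.na(fi)) next
    truth$f50_true[k] <- as.Date(gg$timestamp[fi], tz = "UTC")
    truth$no_bloom[k] <- FALSE
    set.seed(substream(config$seed, k, 1000 * stream + 1))
    f50_obs[k] <- truth$f50_true[k] +
      round(rnorm(1, 0, config$bloom_noise_days))
  }
  ok <- !truth$no_bloom
  list(blooms = data.frame(cultivar = rep(cultivar, sum(ok)),
                           season = labs[ok],
                           f50_date = f50_obs[ok], stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate synthetic forcing-test bud-weight trials
#'
#' Weekly collections from November 1 to the end of March. Field buds weigh
#' around 30 mg; the chamber/field mean-weight ratio is drawn around 1.10
#' before the true break date and around 1.45 at or after it (Gaussian
#' noise on the ratio, clipped to stay on the correct side of the 1.30
#' criterion), so [forcing_break_date()] recovers the truth to within the
#' weekly sampling resolution.
#'
#' @param truth Data frame `season`, `break_date` (see [gen_bloom_records()]).
#' @param config A [synthetic_config()].
#' @param stream Integer stream offset.
#' @param cultivar Cultivar name attached to the trials.
#' @return Long-format data frame `cultivar`, `season`, `collection_date`,
#'   `context`, `weight_mg` (10 buds per context per collection).
#' @export
gen_bud_weight_trials <- function(truth, config, stream = 0,
                                  cultivar = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  rows <- list()
  for (k in seq_len(nrow(truth))) {
    bd <- truth$break_date[k]
    if (is.na(bd)) next
    s <- season(truth$season[k])
    dates <- seq(as.Date(sprintf("%04d-11-01", s$first_year)),
                 as.Date(sprintf("%04d-03-31", s$second_year)), by = 7)
    set.seed(substream(config$seed, k, 1000 * stream + 2))
    for (d in seq_along(dates)) {
      released <- dates[d] >= bd
      base_ratio <- if (released) 1.45 else 1.10
      ratio <- base_ratio + rnorm(1, 0, config$bud_ratio_noise)
      ratio <- if (released) max(ratio, 1.35) else min(ratio, 1.25)
      fm <- 30
      jitter_sd <- 10 * config$bud_ratio_noise
      fw <- fm + rnorm(10, 0, jitter_sd)
      cw <- fm * ratio + rnorm(10, 0, jitter_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        cultivar = cultivar, season = truth$season[k],
        collection_date = dates[d],
        context = rep(c("field", "chamber"), each = 10),
        weight_mg = c(fw, cw), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic biomarker break dates
#'
#' The observed biomarker date (e.g. male-meiosis onset) is the true break
#' date plus rounded Gaussian day jitter.
#'
#' @param truth Data frame `season`, `break_date`.
#' @param config A [synthetic_config()].
#' @param jitter_days SD of the date jitter (days).
#' @param stream Integer stream offset.
#' @param cultivar Cultivar name attached to the records.
#' @return Data frame `cultivar`, `season`, `break_date`.
#' @export
gen_biomarker_dates <- function(truth, config, jitter_days = 2, stream = 0,
                                cultivar = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  keep <- !is.na(truth$break_date)
  set.seed(substream(config$seed, 1, 1000 * stream + 3))
  jit <- round(rnorm(sum(keep), 0, jitter_days))
  data.frame(cultivar = cultivar, season = truth$season[keep],
             break_date = truth$break_date[keep] + jit,
             stringsAsFactors = FALSE)
}

#' End-to-end parameter-recovery experiment
#'
#' Simulates `n_cultivars` independent cultivar/site replicates, each with
#' its own multi-season hourly weather and a sequential-model ground truth
#' (CR* drawn uniformly over `cr_range`, HR* over `hr_range`), runs the
#' correlation and PLS break-date estimators on the observable records
#' only, and scores each estimate against the hidden truth: the error of
#' the break date (days, versus the mean true break across seasons) and of
#' the implied chilling requirement (mean Dynamic CP accumulated to the
#' estimated date, versus CR*).
#'
#' @param n_cultivars Number of simulated cultivars.
#' @param n_seasons Seasons per cultivar.
#' @param seed Master seed.
#' @param cr_range,hr_range Uniform ranges for the true CR* (CP) and HR*
#'   (GDH).
#' @param day_tol,cp_tol Recovery tolerances: days and CP.
#' @param config_args Further arguments passed to [synthetic_config()].
#' @return A data frame with one row per cultivar (`cr_star`, `hr_star`,
#'   truth and estimated break day indices, CP errors, recovery flags) with
#'   summary recovery rates attached as attribute `rates`
#'   (`correlation`, `pls`: fraction of cultivars whose break date is
#'   within `day_tol` days and implied CR within `cp_tol` CP).
#' @export
recovery_experiment <- function(n_cultivars = 100, n_seasons = 20, seed = 1,
                                cr_range = c(45, 85), hr_range = c(3500, 5500),
                                day_tol = 10, cp_tol = 8,
                                config_args = list()) {
  res <- vector("list", n_cultivars)
  for (k in seq_len(n_cultivars)) {
    set.seed(substream(seed, k, 999))
    cr_k <- runif(1, cr_range[1], cr_range[2])
    hr_k <- runif(1, hr_range[1], hr_range[2])
    cfg <- do.call(synthetic_config, c(
      list(n_seasons = n_seasons, seed = seed, cr_star = cr_k, hr_star = hr_k),
      config_args))
    weather <- gen_weather(cfg, stream = k)
    gb <- gen_bloom_records(weather, cfg, stream = k)
    blooms <- gb$blooms
    ok_truth <- !gb$truth$no_bloom
    truth_idx <- mean(vapply(which(ok_truth), function(i) {
      as.numeric(day_of_season(gb$truth$break_date[i], season(gb$truth$season[i])))
    }, numeric(1)))
    mean_cp_at <- function(idx) {
      if (is.na(idx)) return(NA_real_)
      mean(vapply(names(weather), function(sl) {
        chilling_requirement(weather[[sl]], season(sl),
                             season_date(idx, season(sl)), "dynamic")
      }, numeric(1)))
    }
    corr <- tryCatch(
      suppressWarnings(estimate_break_correlation(weather, blooms)),
      error = function(e) list(status = "error", day_index = NA_integer_))
    pls <- tryCatch(
      suppressWarnings(estimate_break_pls(weather, blooms)),
      error = function(e) list(status = "error", break_day = NA_integer_))
    corr_idx <- if (identical(corr$status, "ok")) corr$day_index else NA_integer_
    pls_idx <- if (!is.null(pls$break_day) && !is.na(pls$break_day))
      pls$break_day else NA_integer_
    corr_cp <- mean_cp_at(corr_idx)
    pls_cp <- mean_cp_at(pls_idx)
    res[[k]] <- data.frame(
      cultivar = k, cr_star = cr_k, hr_star = hr_k,
      truth_day = truth_idx,
      corr_day = corr_idx, pls_day = pls_idx,
      corr_day_err = corr_idx - truth_idx, pls_day_err = pls_idx - truth_idx,
      corr_cp_err = corr_cp - cr_k, pls_cp_err = pls_cp - cr_k)
  }
  out <- do.call(rbind, res)
  ok <- function(de, ce) !is.na(de) & !is.na(ce) & abs(de) <= day_tol & abs(ce) <= cp_tol
  out$corr_recovered <- ok(out$corr_day_err, out$corr_cp_err)
  out$pls_recovered <- ok(out$pls_day_err, out$pls_cp_err)
  attr(out, "rates") <- c(correlation = mean(out$corr_recovered),
                          pls = mean(out$pls_recovered))
  out
}
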