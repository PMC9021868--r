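make_trials <- function(ratios, start = "2017-01-01") {
  dts <- as.Date(start) + 7 * (seq_along(ratios) - 1)
  do.call(rbind, lapply(seq_along(ratios), function(i) {
    data.frame(cultivar = "x", collection_date = dts[i],
               context = rep(c("field", "chamber"), each = 10),
               weight_mg = c(rep(10, 10), rep(10 * ratios[i], 10)))
  }))
}

test_that("forcing criterion fires at an inclusive 30% mean weight increase", {
  expect_equal(forcing_break_date(make_trials(c(1.1, 1.31)))$date,
               as.Date("2017-01-08"))                     # 31% met
  expect_equal(forcing_break_date(make_trials(c(1.29)))$status,
               "not_released")                            # 29% not met
  res <- forcing_break_date(make_trials(c(1.2, 1.30, 1.5)))
  expect_equal(res$date, as.Date("2017-01-08"))           # boundary inclusive
  expect_equal(res$status, "released")
  # first qualifying date wins even if later ratios drop again
  expect_equal(forcing_break_date(make_trials(c(1.4, 1.1)))$date,
               as.Date("2017-01-01"))
})

test_that("critical PCC reproduces the t-quantile identity and its limits", {
  expect_equal(round(critical_pcc(13, 0.05), 3), 0.553)
  t1 <- qt(0.975, 1)
  expect_equal(critical_pcc(3, 0.05), t1 / sqrt(t1^2 + 1))
  expect_lt(critical_pcc(3, 1 - 1e-9), 1e-4)              # alpha -> 1 limit
  expect_error(critical_pcc(2), "at least 3")
  # strictly decreasing in n, and r^2 = t^2/(t^2+df) on random (n, alpha)
  r <- vapply(3:40, critical_pcc, numeric(1))
  expect_true(all(diff(r) < 0))
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:50, 1); a <- runif(1, 0.001, 0.5)
    rr <- critical_pcc(n, a); tt <- qt(1 - a / 2, n - 2)
    expect_equal(rr^2, tt^2 / (tt^2 + n - 2))
  }
})

# daily means for n seasons with prescribed per-day values on the grid
grid_daily_means <- function(value_fun, n_seasons = 13, first_year = 2000) {
  do.call(rbind, lapply(seq_len(n_seasons), function(k) {
    s <- season(first_year + k - 1)
    dates <- seq(s$start, s$end, by = "day")
    data.frame(season = s$label, date = dates,
               tmean = value_fun(k, day_of_season(dates, s)))
  }))
}

test_that("correlation profile matches the direct Pearson formula", {
  set.seed(31)
  vals <- matrix(rnorm(13 * 250, 8, 4), nrow = 13)
  dm <- grid_daily_means(function(k, idx) vals[k, idx + 31])
  blooms <- data.frame(season = sprintf("%d-%d", 2000:2012, 2001:2013),
                       f50_date = as.Date(sprintf("%d-03-15", 2001:2013)) +
                         sample(-10:10, 13, replace = TRUE))
  prof <- correlation_profile(dm, blooms)
  expect_equal(attr(prof, "crit_r"), critical_pcc(13, 0.05))
  bloom_doy <- vapply(1:13, function(k)
    as.numeric(day_of_season(blooms$f50_date[k], season(1999 + k))), numeric(1))
  for (d in c(1, 8, 100, 212)) {
    w <- vapply(1:13, function(k)
      mean(vals[k, (max(1, d - 7):min(212, d + 7)) + 31]), numeric(1))
    expect_equal(prof$pcc[d], pearson_oracle(w, bloom_doy), tolerance = 1e-9)
  }
})

test_that("correlation profile handles degenerate and constructed responses", {
  dm <- grid_daily_means(function(k, idx) 8 + k * 0.1 + 0.01 * idx)
  same <- data.frame(season = sprintf("%d-%d", 2000:2012, 2001:2013),
                     f50_date = as.Date(vapply(1:13, function(k)
                       as.character(season_date(160, season(1999 + k))),
                       character(1))))
  prof <- correlation_profile(dm, same)
  expect_true(attr(prof, "zero_variance"))
  expect_true(all(prof$pcc == 0))

  # bloom an exact linear function of the day-40 window mean: pcc(40) = 1
  dm2 <- grid_daily_means(function(k, idx) 8 + k * ((idx >= 33) & (idx <= 47)))
  w40 <- vapply(1:13, function(k) {
    sub <- dm2[dm2$season == sprintf("%d-%d", 1999 + k, 2000 + k), ]
    mean(sub$tmean[day_of_season(sub$date, season(1999 + k)) %in% 33:47])
  }, numeric(1))
  blooms2 <- data.frame(season = sprintf("%d-%d", 2000:2012, 2001:2013),
                        f50_date = vapply(1:13, function(k)
                          as.character(season_date(150 + round(3 * w40[k]),
                                                   season(1999 + k))), character(1)))
  blooms2$f50_date <- as.Date(blooms2$f50_date)
  prof2 <- correlation_profile(dm2, blooms2)
  expect_equal(prof2$pcc[40], 1, tolerance = 1e-9)

  # invariance to shifting all bloom dates; sign flip under negation
  bloom_doy <- vapply(1:13, function(k)
    as.numeric(day_of_season(blooms2$f50_date[k], season(1999 + k))), numeric(1))
  shifted <- blooms2
  shifted$f50_date <- shifted$f50_date + 7
  expect_equal(correlation_profile(dm2, shifted)$pcc, prof2$pcc,
               tolerance = 1e-9)
  # seasons lacking bloom data are dropped with a warning
  expect_warning(correlation_profile(dm2, blooms2[-13, ], min_years = 11),
                 "dropping")
})

fake_profile <- function(pcc, crit = 0.5) {
  out <- data.frame(day = seq_along(pcc), pcc = pcc)
  attr(out, "crit_r") <- crit
  class(out) <- c("correlation_profile", "data.frame")
  out
}

test_that("transition mid-point break date rounds half-up and flags failures", {
  p <- rep(0, 212); p[1:40] <- 0.6; p[60:80] <- -0.6
  res <- correlation_break_date(fake_profile(p))
  expect_equal(res[c("last_positive", "first_negative", "day_index")],
               list(last_positive = 40L, first_negative = 60L, day_index = 50L))
  p2 <- rep(0, 212); p2[1:40] <- 0.6; p2[61:80] <- -0.6
  expect_equal(correlation_break_date(fake_profile(p2))$day_index, 51L)

  expect_equal(correlation_break_date(fake_profile(rep(0, 212)))$status,
               "undetermined")
  p3 <- rep(0, 212); p3[50] <- 0.6; p3[20] <- -0.6    # negative only before L
  expect_equal(correlation_break_date(fake_profile(p3))$status, "undetermined")
})

test_that("biomarker dates pass through and average on the season ordinal", {
  one <- biomarker_break_dates(data.frame(season = "2018-2019",
                                          break_date = as.Date("2019-01-20")))
  expect_equal(one$mean_date, as.Date("2019-01-20"))

  two <- biomarker_break_dates(data.frame(
    season = c("2018-2019", "2019-2020"),
    break_date = as.Date(c("2019-01-12", "2020-01-30"))))
  expect_equal(two$mean_date, as.Date("2020-01-21"))

  set.seed(3)
  seasons <- sprintf("%d-%d", 2010:2017, 2011:2018)
  offs <- sample(80:140, 8)
  recs <- data.frame(season = seasons, break_date = as.Date(vapply(
    1:8, function(k) as.character(season_date(offs[k], season(2009 + k))),
    character(1))))
  est <- biomarker_break_dates(recs)
  expect_equal(est$mean_day_index, as.integer(floor(mean(offs) + 0.5)))
})
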