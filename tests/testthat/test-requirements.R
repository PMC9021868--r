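# a season with a warm autumn block then constant cold, built exactly
two_phase_season <- function(first_year = 2016, warm_days = 30,
                             warm_c = 25, cold_c = 6) {
  s <- season(first_year)
  n <- as.integer(s$end - s$start + 1)
  temps <- c(rep(warm_c, warm_days * 24), rep(cold_c, (n - warm_days) * 24))
  make_series(temps, paste(s$start, "00:00:00"))
}

test_that("chilling requirement applies each model's accumulation start rule", {
  ser <- two_phase_season()
  s <- season(2016)

  # Weinberger: every sub-7.2 hour counts from the first cold hour
  expect_equal(chilling_requirement(ser, s, as.Date("2016-10-05"), "weinberger"),
               5 * 24)
  # the warm autumn contributes nothing and precedes the start
  expect_warning(
    z <- chilling_requirement(ser, s, as.Date("2016-09-10"), "weinberger"),
    "precedes")
  expect_equal(z, 0)

  # Utah: warm autumn drives CU to its minimum on the last warm day;
  # accumulation restarts there, so a break on that day is 0
  expect_equal(chilling_requirement(ser, s, as.Date("2016-09-30"), "utah"), 0)
  expect_equal(chilling_requirement(ser, s, as.Date("2016-10-10"), "utah"),
               10 * 24)

  # Dynamic: equals the oracle accumulation to 24:00 of the break date
  bd <- as.Date("2016-12-15")
  hours_to_bd <- as.integer(bd - s$start + 1) * 24
  expect_equal(chilling_requirement(ser, s, bd, "dynamic"),
               dyn_oracle(ser$temp_c[seq_len(hours_to_bd)])$cumulative[hours_to_bd],
               tolerance = 1e-9)
  expect_error(chilling_requirement(ser, s, as.Date("2017-06-01"), "dynamic"),
               "outside season")
})

test_that("chilling requirement is monotone in the break date for monotone models", {
  set.seed(19)
  cfg <- synthetic_config(n_seasons = 1, seed = 19)
  ser <- gen_weather(cfg)[[1]]
  s <- season(2000)
  dates <- s$start + c(30, 60, 90, 120, 180, 240)
  for (m in c("dynamic", "weinberger")) {
    vals <- suppressWarnings(vapply(dates, function(d)
      chilling_requirement(ser, s, d, m), numeric(1)))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("heat requirement covers the closed break-to-bloom day span additively", {
  ser <- two_phase_season(warm_days = 0, cold_c = 14.5)  # constant 14.5
  b <- as.Date("2017-03-01")
  expect_equal(heat_requirement(ser, b, b + 9), 2400)    # 10 d x 240 GDH
  expect_equal(heat_requirement(ser, b, b), 240)
  cold <- two_phase_season(warm_days = 0, cold_c = 2)
  expect_equal(heat_requirement(cold, b, b), 0)          # all hours below base
  expect_error(heat_requirement(ser, b, b - 1), "precedes")
  # additivity: [b, f1] + (f1, f2] = [b, f2]
  f1 <- b + 9; f2 <- b + 20
  expect_equal(heat_requirement(ser, b, f1) +
                 heat_requirement(ser, f1 + 1, f2),
               heat_requirement(ser, b, f2))
})

test_that("cultivar summaries use the sample SD and percent cv", {
  expect_equal(summarize_cultivar(c(100, 100))[c("mean", "sd", "cv")],
               list(mean = 100, sd = 0, cv = 0))
  one <- summarize_cultivar(100)
  expect_true(one$single)
  expect_equal(one$sd, 0)
  two <- summarize_cultivar(c(90, 110))
  expect_equal(two$mean, 100)
  expect_equal(two$sd, 14.142136, tolerance = 1e-6)
  expect_equal(two$cv, 14.142136, tolerance = 1e-6)
  expect_true(is.na(summarize_cultivar(c(-5, 5))$cv))
})

test_that("classification bands reproduce the published thresholds", {
  expect_equal(classify_cr(84.8), "high")
  expect_equal(classify_cr(66), "high")
  expect_equal(classify_cr(65.9), "medium")
  expect_equal(classify_cr(56), "medium")
  expect_equal(classify_cr(53.2), "low_medium")
  expect_equal(classify_cr(49.9), "below_range")
  expect_equal(classify_hr(4284), "high")
  expect_equal(classify_hr(4101), "high")
  expect_equal(classify_hr(4000), "medium")
  expect_equal(classify_hr(3900.5), "medium")   # integer gap closed upward
  expect_equal(classify_hr(3900), "low")
  # order preservation: a larger value never maps to a lower class
  set.seed(2)
  v <- sort(runif(200, 0, 120))
  ranks_cr <- match(classify_cr(v), c("below_range", "low_medium", "medium", "high"))
  expect_true(all(diff(ranks_cr) >= 0))
  v2 <- sort(runif(200, 0, 6000))
  ranks_hr <- match(classify_hr(v2), c("low", "medium", "high"))
  expect_true(all(diff(ranks_hr) >= 0))
})

test_that("requirements_table summarises per-season and fixed-date methods", {
  cfg <- synthetic_config(n_seasons = 3, seed = 5, cr_star = 50, hr_star = 4000)
  w <- gen_weather(cfg)
  gb <- gen_bloom_records(w, cfg)
  # per-season break dates (biomarker-style)
  res <- requirements_table(w, gb$blooms,
                            gb$truth[, c("season", "break_date")])
  expect_equal(res$dynamic$n, 3)
  # accumulation stops within one day of CR*: mean close to 50 CP
  expect_lt(abs(res$dynamic$mean - 50), 2)
  expect_true(all(res$weinberger$per_season >= 0))
  expect_equal(res$hr$class, classify_hr(res$hr$mean))
  # fixed day-of-season index (statistical-style): SD across seasons
  mean_idx <- round(mean(vapply(seq_len(3), function(i)
    as.numeric(day_of_season(gb$truth$break_date[i],
                             season(gb$truth$season[i]))), numeric(1))))
  res2 <- requirements_table(w, gb$blooms, mean_idx, models = "dynamic")
  expect_equal(res2$break_day_index, as.integer(mean_idx))
  expect_gte(res2$dynamic$sd, 0)
  expect_equal(unname(res2$dynamic$mean),
               mean(vapply(names(w), function(sl)
                 chilling_requirement(w[[sl]], season(sl),
                                      season_date(mean_idx, season(sl)),
                                      "dynamic"), numeric(1))))
})
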