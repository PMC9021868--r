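test_that("weather generator is deterministic with the documented structure", {
  flat <- synthetic_config(n_seasons = 1, seed = 1, annual_amplitude_c = 0,
                           diurnal_amplitude_c = 0, innovation_sd_c = 0,
                           interannual_sd_c = 0)
  w <- gen_weather(flat)[[1]]
  expect_true(all(w$temp_c == 15))                 # constant at annual mean
  expect_equal(nrow(w), as.integer(242 * 24))      # Sep 1 .. Apr 30, hourly

  cfg <- synthetic_config(n_seasons = 3, seed = 99)
  expect_identical(gen_weather(cfg), gen_weather(cfg))      # same seed
  other <- gen_weather(cfg, stream = 1)
  expect_false(identical(gen_weather(cfg)[[1]]$temp_c, other[[1]]$temp_c))

  # generated records pass the temperature validator without warnings
  expect_silent(validate_temperature_series(gen_weather(cfg)[[2]]))
})

test_that("season chill totals vary between years under the default climate", {
  cfg <- synthetic_config(n_seasons = 20, seed = 2)
  w <- gen_weather(cfg)
  totals <- vapply(w, function(s) {
    cs <- dynamic_chill_portions(s)
    cs$cumulative[nrow(cs)]
  }, numeric(1))
  expect_gt(var(totals), 0)
  expect_true(all(totals > 50))                    # ample chill every winter
})

test_that("bloom generation inverts the sequential chill-then-heat truth", {
  cfg <- synthetic_config(n_seasons = 4, seed = 8, cr_star = 50,
                          hr_star = 4000, bloom_noise_days = 0)
  w <- gen_weather(cfg)
  gb <- gen_bloom_records(w, cfg)
  expect_true(all(!gb$truth$no_bloom))
  # noiseless observation: F50 equals the truth fulfilment date
  expect_equal(gb$blooms$f50_date, gb$truth$f50_true)

  for (k in seq_len(4)) {
    ser <- w[[k]]
    cp <- dynamic_chill_portions(ser)
    bi <- which(as.Date(cp$timestamp, tz = "UTC") == gb$truth$break_date[k])
    # CP crosses CR* during the break day and not before it
    expect_gte(max(cp$cumulative[bi]), 50)
    expect_lt(cp$cumulative[min(bi) - 1], 50 + 1e-9)
    # self-consistency: CP at the break hour is within one hour's
    # accumulation of CR*
    cross <- which(cp$cumulative >= 50)[1]
    expect_lte(cp$cumulative[cross] - 50, cp$contribution[cross] + 1e-12)
  }

  zero <- synthetic_config(n_seasons = 1, seed = 8, cr_star = 0)
  gz <- gen_bloom_records(gen_weather(zero), zero)
  expect_equal(gz$truth$break_date, as.Date("2000-09-01"))

  unreachable <- synthetic_config(n_seasons = 1, seed = 8, cr_star = 1e6)
  gu <- gen_bloom_records(gen_weather(unreachable), unreachable)
  expect_true(gu$truth$no_bloom)
  expect_equal(nrow(gu$blooms), 0)
})

test_that("synthetic bud-weight trials recover the truth at weekly resolution", {
  cfg0 <- synthetic_config(n_seasons = 3, seed = 12, bud_ratio_noise = 0)
  w <- gen_weather(cfg0)
  truth <- gen_bloom_records(w, cfg0)$truth
  trials <- gen_bud_weight_trials(truth, cfg0)
  expect_identical(trials, gen_bud_weight_trials(truth, cfg0))  # same seed
  for (sl in truth$season) {
    sub <- trials[trials$season == sl, ]
    got <- forcing_break_date(sub)
    weekly <- sort(unique(sub$collection_date))
    expect_equal(got$date,
                 weekly[weekly >= truth$break_date[truth$season == sl]][1])
  }
  # long-format trials pass the records_io reader round-trip
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(trials, f, row.names = FALSE)
  expect_silent(back <- read_bud_weight_trials(f))
  expect_equal(nrow(back), nrow(trials))
})

test_that("noisy ratio trials still localise the break within two weeks", {
  cfg <- synthetic_config(n_seasons = 1, seed = 31, bud_ratio_noise = 0.05)
  w <- gen_weather(cfg)
  truth <- gen_bloom_records(w, cfg)$truth
  hits <- 0L
  for (rep in 1:100) {
    cfg_r <- synthetic_config(n_seasons = 1, seed = 31 + rep,
                              bud_ratio_noise = 0.05)
    trials <- gen_bud_weight_trials(truth, cfg_r)
    got <- forcing_break_date(trials)
    if (!is.na(got$date) &&
        abs(as.numeric(got$date - truth$break_date[1])) <= 14) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 90L)
})

test_that("biomarker-implied requirements agree with the truth by Bland-Altman", {
  truth_cr <- est_cr <- numeric(6)
  for (k in 1:6) {
    set.seed(chillreq:::substream(77, k, 0))
    cr_k <- runif(1, 45, 85)
    cfg <- synthetic_config(n_seasons = 6, seed = 77, cr_star = cr_k)
    w <- gen_weather(cfg, stream = k)
    truth <- gen_bloom_records(w, cfg, stream = k)$truth
    bio <- gen_biomarker_dates(truth, cfg, jitter_days = 2, stream = k)
    vals <- vapply(seq_len(nrow(bio)), function(i)
      chilling_requirement(w[[bio$season[i]]], season(bio$season[i]),
                           bio$break_date[i], "dynamic"), numeric(1))
    truth_cr[k] <- cr_k
    est_cr[k] <- mean(vals)
  }
  ba <- bland_altman(est_cr, truth_cr, pair = c("biomarker", "truth"))
  expect_lt(abs(ba$mean_diff), 5)
})

test_that("biomarker jitter keeps the pass-through nearly unbiased", {
  cfg <- synthetic_config(n_seasons = 8, seed = 14)
  w <- gen_weather(cfg)
  truth <- gen_bloom_records(w, cfg)$truth
  bio <- gen_biomarker_dates(truth, cfg, jitter_days = 2)
  expect_equal(nrow(bio), 8)
  est <- biomarker_break_dates(bio)
  truth_idx <- mean(vapply(seq_len(8), function(i)
    as.numeric(day_of_season(truth$break_date[i], season(truth$season[i]))),
    numeric(1)))
  expect_lt(abs(est$mean_day_index - truth_idx), 3)
  # records round-trip through the biomarker reader
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(bio, f, row.names = FALSE)
  expect_silent(back <- read_biomarker_dates(f))
  expect_equal(back$break_date, bio$break_date)
})
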