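# Fitbit and Empatica providers.

eda_rows <- function(values, start = "2020-01-01 10:00:00") {
  data.table(timestamp = utc_ms(start) + seq_along(values) * 60000,
             electrodermal_activity = values)
}

test_that("empatica value statistics match the worked oracle", {
  qa <- quick_assign(eda_rows(c(1, 1, 2, 3)))
  fr <- empatica_stream_features(qa$assigned, qa$instances,
                                 "empatica_electrodermal_activity")
  g <- function(n) feature_value(
    fr, paste0("rapids_empatica_electrodermal_activity_", n))
  expect_equal(g("avgeda"), 1.75)
  expect_equal(g("medianeda"), 1.5)
  expect_equal(g("modeeda"), 1)
  expect_equal(g("diffmaxmodeeda"), 2)
  expect_equal(g("diffminmodeeda"), 0)
  h <- -(0.5 * log(0.5) + 0.25 * log(0.25) + 0.25 * log(0.25))
  expect_equal(g("entropyeda"), h, tolerance = 1e-9)
  expect_equal(round(h, 4), 1.0397)
  # constant stream: std 0, entropy 0
  qc <- quick_assign(eda_rows(rep(2.5, 6)))
  fc <- empatica_stream_features(qc$assigned, qc$instances,
                                 "empatica_electrodermal_activity")
  expect_equal(feature_value(fc,
                             "rapids_empatica_electrodermal_activity_stdeda"),
               0)
  expect_equal(feature_value(fc,
                             "rapids_empatica_electrodermal_activity_entropyeda"),
               0)
  # empty -> all NA
  fe <- empatica_stream_features(qa$assigned[0], qa$instances,
                                 "empatica_electrodermal_activity")
  expect_true(is.na(feature_value(fe,
                                  "rapids_empatica_electrodermal_activity_avgeda")))
})

test_that("heart-rate intraday zones bin the oracle samples 1/1/1/1", {
  qa <- quick_assign(data.table(
    timestamp = utc_ms("2020-01-01 09:00:00") + (1:4) * 60000,
    heartrate = c(70, 100, 140, 170)))
  fr <- heart_rate_intraday_features(qa$assigned, qa$instances,
                                     heart_rate_zones(c(90, 120, 160)))
  g <- function(n) feature_value(fr, paste0("rapids_fitbit_heartrate_intraday_",
                                            n))
  expect_equal(g("minutesonoutofrangezone"), 1)
  expect_equal(g("minutesonfatburnzone"), 1)
  expect_equal(g("minutesoncardiozone"), 1)
  expect_equal(g("minutesonpeakzone"), 1)
  expect_equal(g("maxhr"), 170)
  # all in fat-burn
  qb <- quick_assign(data.table(
    timestamp = utc_ms("2020-01-01 09:00:00") + (1:3) * 60000,
    heartrate = c(95, 100, 105)))
  fb <- heart_rate_intraday_features(qb$assigned, qb$instances)
  expect_equal(feature_value(fb,
                             "rapids_fitbit_heartrate_intraday_minutesonfatburnzone"),
               3)
  expect_equal(feature_value(fb,
                             "rapids_fitbit_heartrate_intraday_minutesoncardiozone"),
               0)
  # empty -> zone minutes 0
  f0 <- heart_rate_intraday_features(qa$assigned[0], qa$instances)
  expect_equal(feature_value(f0,
                             "rapids_fitbit_heartrate_intraday_minutesonpeakzone"),
               0)
  expect_error(heart_rate_zones(c(120, 90, 160)), "ascending")
})

test_that("zone minutes conserve the sample count", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    qa <- quick_assign(data.table(
      timestamp = utc_ms("2020-01-01 00:00:00") + (1:n) * 60000,
      heartrate = round(runif(n, 45, 190))))
    fr <- heart_rate_intraday_features(qa$assigned, qa$instances)
    zm <- sum(unlist(fr[1, grep("minuteson", names(fr)), with = FALSE]))
    expect_equal(zm, n)
  }
})

test_that("steps intraday: bouts follow the run-length oracle", {
  t0 <- utc_ms("2020-01-01 09:00:00")
  qa <- quick_assign(data.table(
    timestamp = t0 + (0:59) * 60000,
    steps = c(rep(0, 30), rep(100, 30))))
  fr <- steps_intraday_features(qa$assigned, qa$instances)
  g <- function(n) feature_value(fr, paste0("rapids_fitbit_steps_intraday_", n))
  expect_equal(g("sumsteps"), 3000)
  expect_equal(g("countepisodesedentarybout"), 1)
  expect_equal(g("sumdurationsedentarybout"), 30)
  expect_equal(g("countepisodeactivebout"), 1)
  expect_equal(g("sumdurationactivebout"), 30)
  # all zeros
  qz <- quick_assign(data.table(timestamp = t0 + (0:9) * 60000, steps = 0))
  fz <- steps_intraday_features(qz$assigned, qz$instances)
  expect_equal(feature_value(fz,
                             "rapids_fitbit_steps_intraday_countepisodesedentarybout"),
               1)
  expect_equal(feature_value(fz,
                             "rapids_fitbit_steps_intraday_countepisodeactivebout"),
               0)
  # alternating 0/100 -> 5 bouts each of duration 1
  qalt <- quick_assign(data.table(timestamp = t0 + (0:9) * 60000,
                                  steps = rep(c(0, 100), 5)))
  falt <- steps_intraday_features(qalt$assigned, qalt$instances)
  expect_equal(feature_value(falt,
                             "rapids_fitbit_steps_intraday_countepisodesedentarybout"),
               5)
  expect_equal(feature_value(falt,
                             "rapids_fitbit_steps_intraday_countepisodeactivebout"),
               5)
  expect_equal(feature_value(falt,
                             "rapids_fitbit_steps_intraday_maxdurationactivebout"),
               1)
  # bout durations reconstruct the sampled span
  expect_equal(feature_value(falt,
                             "rapids_fitbit_steps_intraday_sumdurationsedentarybout") +
                 feature_value(falt,
                               "rapids_fitbit_steps_intraday_sumdurationactivebout"),
               10)
})

test_that("summary providers consume daily records", {
  inst <- expand_periodic(segment_spec("week", "periodic", "7d"),
                          as.Date("2020-01-01"), "p01", UTC_TZH)
  days <- seq(as.Date("2020-01-01"), by = "day", length.out = 7)
  stp <- data.table(timestamp = utc_ms(paste(days, "00:00:00")) + 1,
                    local_date = as.character(days),
                    steps = c(4000, 6000, 8000, 10000, 12000, 9000, 7000))
  a <- assign_rows(stp, inst)
  fr <- steps_summary_features(a, inst)
  expect_equal(feature_value(fr, "rapids_fitbit_steps_summary_maxsumsteps"),
               12000)
  expect_equal(feature_value(fr, "rapids_fitbit_steps_summary_avgsumsteps"),
               mean(stp$steps))

  hr <- data.table(timestamp = utc_ms(paste(days, "00:00:00")) + 1,
                   local_date = as.character(days),
                   heartrate_daily_restinghr = c(60, 62, 61, 63, 60, 59, 61))
  for (z in c("outofrange", "fatburn", "cardio", "peak")) {
    hr[, (paste0("heartrate_", z, "_minutes")) := 10]
    hr[, (paste0("heartrate_", z, "_calories")) := 100]
  }
  fh <- heartrate_summary_features(assign_rows(hr, inst), inst)
  expect_equal(feature_value(fh,
                             "rapids_fitbit_heartrate_summary_avgrestinghr"),
               mean(hr$heartrate_daily_restinghr))
  expect_equal(feature_value(fh,
                             "rapids_fitbit_heartrate_summary_summinutescardiozone"),
               70)
  expect_identical(sum(grepl("fitbit_heartrate_summary", names(fh))), 37L)

  slp <- data.table(timestamp = utc_ms(paste(days[1:3], "23:00:00")),
                    local_date = as.character(days[1:3]),
                    type = c("main", "main", "nap"),
                    duration_ms = c(8, 7, 1) * 3.6e6,
                    minutes_asleep = c(430, 390, 55),
                    minutes_awake = c(50, 30, 5),
                    efficiency = c(90, 93, 92))
  fs <- sleep_summary_features(assign_rows(slp, inst), inst)
  expect_equal(feature_value(fs,
                             "rapids_fitbit_sleep_summary_countepisodemain"), 2)
  expect_equal(feature_value(fs,
                             "rapids_fitbit_sleep_summary_countepisodeall"), 3)
  expect_equal(feature_value(fs,
                             "rapids_fitbit_sleep_summary_sumdurationasleepmain"),
               820)
  expect_identical(sum(grepl("fitbit_sleep_summary", names(fs))), 36L)
})

test_that("sleep intraday providers consume stage fragments", {
  inst <- daily_instances("2020-01-01")
  rows <- data.table(
    timestamp = utc_ms("2020-01-01 01:00:00") + (0:239) * 60000,
    level = rep(c("light", "deep", "rem", "light", "awake", "light"),
                each = 40),
    type = "main")
  frags <- split_on_boundaries(sleep_episodes(rows), inst)
  fr <- sleep_intraday_features(frags, inst)
  g <- function(n) feature_value(fr, paste0("rapids_fitbit_sleep_intraday_", n))
  expect_equal(g("countepisodelight"), 3)
  expect_equal(g("sumdurationlight"), 120)
  expect_equal(g("sumdurationdeep"), 40)
  expect_equal(g("ratioasleepinbed"), 200 / 240)
  expect_identical(sum(grepl("rapids_fitbit_sleep_intraday", names(fr))), 21L)

  fp <- sleep_intraday_price_features(frags, inst)
  gp <- function(n) feature_value(fp, paste0("price_fitbit_sleep_intraday_", n))
  expect_equal(gp("countepisodeall"), 6)
  expect_equal(gp("sumdurationall"), 240)
  expect_equal(gp("ratioawakeinbed"), 40 / 240)
  expect_equal(gp("firstbedtime"), 60)    # 01:00 local
  expect_equal(gp("lastwaketime"), 300)   # 05:00 local
  expect_equal(gp("countdaysleep"), 1)
  expect_identical(sum(grepl("price_fitbit_sleep_intraday", names(fp))), 13L)
})

test_that("calories intraday aggregates levels and episodes", {
  t0 <- utc_ms("2020-01-01 08:00:00")
  qa <- quick_assign(data.table(
    timestamp = t0 + (0:9) * 60000,
    calories = c(rep(1.2, 5), rep(5, 3), rep(1.2, 2)),
    level = c(rep("sedentary", 5), rep("fairlyactive", 3),
              rep("sedentary", 2))))
  fr <- calories_intraday_features(qa$assigned, qa$instances)
  g <- function(n) feature_value(fr,
                                 paste0("rapids_fitbit_calories_intraday_", n))
  expect_equal(g("minutessedentary"), 7)
  expect_equal(g("caloriesfairlyactive"), 15)
  expect_equal(g("countepisodesedentary"), 2)
  expect_equal(g("maxdurationepisodesedentary"), 5)
  expect_equal(g("sumcalories"), 1.2 * 7 + 15)
  expect_identical(sum(grepl("fitbit_calories_intraday", names(fr))), 22L)
})

test_that("fitbit data yield reuses the yield engine", {
  inst <- daily_instances("2020-01-01")
  rows <- data.table(timestamp = utc_ms("2020-01-01 00:00:00") +
                       (0:719) * 60000)
  fr <- data_yield_features(assign_rows(rows, inst), inst,
                            sensor = "fitbit_data_yield")
  expect_equal(feature_value(fr,
                             "rapids_fitbit_data_yield_ratiovalidyieldedminutes"),
               0.5)
})
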