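# Phone providers against hand-computed oracles and structural invariants.

.shannon_test <- function(w) { p <- w / sum(w); -sum(p * log(p)) }

call_rows <- function(durations, contacts, type = "incoming",
                      start = "2020-01-01 10:00:00") {
  data.table(timestamp = utc_ms(start) + seq_along(durations) * 60000,
             call_type = type, call_duration = durations, trace = contacts)
}

test_that("call features match the worked oracle", {
  qa <- quick_assign(call_rows(c(60, 120, 180), c("A", "A", "B")))
  fr <- call_features(qa$assigned, qa$instances, "incoming")
  g <- function(n) feature_value(fr, paste0("rapids_calls_incoming_", n))
  expect_equal(g("count"), 3)
  expect_equal(g("distinctcontacts"), 2)
  expect_equal(g("meanduration"), 120)
  expect_equal(g("sumduration"), 360)
  expect_equal(g("minduration"), 60)
  expect_equal(g("maxduration"), 180)
  expect_equal(g("stdduration"), 60)
  expect_equal(g("countmostfrequentcontact"), 2)
  # entropy of weights (60,120,180): -(sum p ln p), p = 1/6, 1/3, 1/2
  h <- -(1/6 * log(1/6) + 1/3 * log(1/3) + 1/2 * log(1/2))
  expect_equal(g("entropyduration"), h, tolerance = 1e-9)
  expect_equal(round(h, 4), 1.0114)
  expect_equal(g("timefirstcall"), 601)  # 10:01 local
  expect_equal(g("timelastcall"), 603)
})

test_that("call features: degenerate and empty cases follow the policy", {
  qa <- quick_assign(call_rows(60, "A"))
  fr <- call_features(qa$assigned, qa$instances, "incoming")
  expect_true(is.na(feature_value(fr, "rapids_calls_incoming_stdduration")))
  expect_equal(feature_value(fr, "rapids_calls_incoming_entropyduration"), 0)
  # zero calls: counts 0, stats NA
  qa2 <- quick_assign(call_rows(60, "A", type = "outgoing"))
  fr2 <- call_features(qa2$assigned, qa2$instances, "incoming")
  expect_equal(feature_value(fr2, "rapids_calls_incoming_count"), 0)
  expect_true(is.na(feature_value(fr2, "rapids_calls_incoming_meanduration")))
  # missed provider has 5 features only
  frm <- call_features(qa$assigned, qa$instances, "missed")
  expect_identical(sum(grepl("calls_missed", names(frm))), 5L)
  # negative durations rejected with warning
  qa3 <- quick_assign(call_rows(c(-5, 60), c("A", "B")))
  expect_warning(fr3 <- call_features(qa3$assigned, qa3$instances,
                                      "incoming"), "negative")
  expect_equal(feature_value(fr3, "rapids_calls_incoming_count"), 1)
})

test_that("entropy is bounded by ln(count) on random inputs", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:15, 1)
    qa <- quick_assign(call_rows(round(runif(n, 1, 900)),
                                 sample(LETTERS[1:4], n, TRUE)))
    fr <- call_features(qa$assigned, qa$instances, "incoming")
    h <- feature_value(fr, "rapids_calls_incoming_entropyduration")
    expect_gte(h, 0)
    expect_lte(h, log(n) + 1e-12)
  }
})

test_that("count/sum features are associative over stream chunks", {
  set.seed(13)
  rows <- call_rows(round(runif(20, 10, 600)), sample(c("A", "B", "C"), 20,
                                                      TRUE))
  qa <- quick_assign(rows)
  whole <- call_features(qa$assigned, qa$instances, "incoming")
  a1 <- quick_assign(rows[1:8]); a2 <- quick_assign(rows[9:20])
  f1 <- call_features(a1$assigned, a1$instances, "incoming")
  f2 <- call_features(a2$assigned, a2$instances, "incoming")
  for (n in c("count", "sumduration")) {
    col <- paste0("rapids_calls_incoming_", n)
    expect_equal(feature_value(whole, col),
                 feature_value(f1, col) + feature_value(f2, col))
  }
  # purity: identical inputs give identical outputs
  expect_identical(whole, call_features(qa$assigned, qa$instances,
                                        "incoming"))
})

test_that("screen features summarize fragments", {
  inst <- daily_instances("2020-01-01")
  frags <- split_on_boundaries(
    data.table(kind = "screen_unlock",
               start_utc_ms = utc_ms(c("2020-01-01 09:00:00",
                                       "2020-01-01 12:00:00")),
               end_utc_ms = utc_ms(c("2020-01-01 09:10:00",
                                     "2020-01-01 12:20:00")),
               truncated = FALSE), inst)
  fr <- screen_features(frags, inst)
  expect_equal(feature_value(fr, "rapids_screen_countepisode"), 2)
  expect_equal(feature_value(fr, "rapids_screen_sumduration"), 30)
  expect_equal(feature_value(fr, "rapids_screen_avgduration"), 15)
  expect_equal(feature_value(fr, "rapids_screen_firstuseafter"), 540)
  # no fragments
  fr0 <- screen_features(frags[0], inst)
  expect_equal(feature_value(fr0, "rapids_screen_countepisode"), 0)
  # fragment starting at segment start
  frags2 <- split_on_boundaries(
    data.table(kind = "screen_unlock",
               start_utc_ms = utc_ms("2020-01-01 00:00:00"),
               end_utc_ms = utc_ms("2020-01-01 00:10:00"),
               truncated = FALSE), inst)
  expect_equal(feature_value(screen_features(frags2, inst),
                             "rapids_screen_firstuseafter"), 0)
})

test_that("light features compute direct statistics", {
  mk <- function(lux) quick_assign(data.table(
    timestamp = utc_ms("2020-01-01 08:00:00") + seq_along(lux) * 60000,
    double_light_lux = lux))
  qa <- mk(c(10, 20, 30))
  fr <- generic_numeric_features(qa$assigned, qa$instances)
  expect_equal(feature_value(fr, "rapids_light_count"), 3)
  expect_equal(feature_value(fr, "rapids_light_avglux"), 20)
  expect_equal(feature_value(fr, "rapids_light_medianlux"), 20)
  qa1 <- mk(5)
  expect_true(is.na(feature_value(
    generic_numeric_features(qa1$assigned, qa1$instances),
    "rapids_light_stdlux")))
  fr0 <- generic_numeric_features(qa$assigned[0], qa$instances)
  expect_equal(feature_value(fr0, "rapids_light_count"), 0)
})

test_that("data yield matches the half-day oracle and clips", {
  inst <- daily_instances("2020-01-01")
  rows <- data.table(timestamp = utc_ms("2020-01-01 00:00:00") +
                       (0:719) * 60000)
  a <- assign_rows(rows, inst)
  fr <- data_yield_features(a, inst)
  expect_equal(feature_value(fr, "rapids_data_yield_ratiovalidyieldedminutes"),
               0.5)
  expect_equal(feature_value(fr, "rapids_data_yield_ratiovalidyieldedhours"),
               0.5)
  # no rows -> both 0
  fr0 <- data_yield_features(a[0], inst)
  expect_equal(feature_value(fr0, "rapids_data_yield_ratiovalidyieldedminutes"),
               0)
  # full coverage -> both 1
  all_rows <- data.table(timestamp = utc_ms("2020-01-01 00:00:00") +
                           (0:1439) * 60000)
  fr1 <- data_yield_features(assign_rows(all_rows, inst), inst)
  expect_equal(feature_value(fr1, "rapids_data_yield_ratiovalidyieldedminutes"),
               1)
  expect_equal(feature_value(fr1, "rapids_data_yield_ratiovalidyieldedhours"),
               1)
  # hour threshold semantics: 20 of 60 minutes < 0.5 -> hour invalid
  sparse <- data.table(timestamp = utc_ms("2020-01-01 00:00:00") +
                         (0:19) * 60000)
  frs <- data_yield_features(assign_rows(sparse, inst), inst,
                             hour_threshold = 0.5)
  expect_equal(feature_value(frs, "rapids_data_yield_ratiovalidyieldedhours"),
               0)
})

test_that("sms, wifi, bluetooth, and app providers emit catalog names", {
  qa <- quick_assign(data.table(
    timestamp = utc_ms("2020-01-01 09:00:00") + (1:4) * 60000,
    message_type = c("sent", "sent", "received", "sent"),
    trace = c("A", "A", "B", "B")))
  fr <- sms_features(qa$assigned, qa$instances)
  expect_equal(feature_value(fr, "rapids_sms_countsent"), 3)
  expect_equal(feature_value(fr, "rapids_sms_countmostfrequentcontactsent"), 2)
  expect_equal(feature_value(fr, "rapids_sms_distinctcontactsreceived"), 1)

  qb <- quick_assign(data.table(
    timestamp = utc_ms("2020-01-01 09:00:00") + (1:5) * 60000,
    bt_address = c("x", "x", "x", "y", "z")))
  fb <- bluetooth_features(qb$assigned, qb$instances)
  expect_equal(feature_value(fb, "rapids_bluetooth_countscans"), 5)
  expect_equal(feature_value(fb, "rapids_bluetooth_uniquedevices"), 3)
  expect_equal(feature_value(fb, "rapids_bluetooth_countscansmostuniquedevice"),
               3)
  fd <- bluetooth_doryab_features(qb$assigned, qb$instances)
  expect_identical(sum(grepl("doryab_bluetooth", names(fd))), 27L)
  # x dominates scans -> own; y, z -> others
  expect_equal(feature_value(fd, "doryab_bluetooth_countscansown"), 3)
  expect_equal(feature_value(fd, "doryab_bluetooth_countscansothers"), 2)

  qw <- quick_assign(data.table(
    timestamp = utc_ms("2020-01-01 09:00:00") + (1:2) * 60000,
    bssid = c("ap1", "ap1")))
  fw <- wifi_features(qw$assigned, qw$instances, "wifi_visible")
  expect_equal(feature_value(fw, "rapids_wifi_visible_countscans"), 2)

  qapp <- quick_assign(data.table(
    timestamp = utc_ms("2020-01-01 09:00:00") + (1:4) * 60000,
    package_name = c("mail", "mail", "maps", "mail"),
    application_name = c("Mail", "Mail", "Maps", "Mail")))
  fa <- app_foreground_features(qapp$assigned, qapp$instances)
  expect_equal(feature_value(fa, "rapids_applications_foreground_count"), 4)
  expect_equal(feature_value(fa,
                             "rapids_applications_foreground_frequencyentropy"),
               .shannon_test(c(3, 1)))
})

test_that("battery, activity, keyboard, accelerometer providers compute", {
  inst <- daily_instances("2020-01-01")
  frags <- split_on_boundaries(battery_episodes(data.table(
    timestamp = utc_ms("2020-01-01 08:00:00") + c(0, 7.2e6),
    battery_level = c(80, 70))), inst)
  fb <- battery_features(frags, inst)
  expect_equal(feature_value(fb, "rapids_battery_countdischarge"), 1)
  expect_equal(feature_value(fb, "rapids_battery_avgconsumptionrate"), 5)
  expect_equal(feature_value(fb, "rapids_battery_sumdurationdischarge"), 120)

  act_rows <- data.table(
    timestamp = utc_ms("2020-01-01 09:00:00") + (0:3) * 60000,
    activity_type = c("still", "still", "walking", "walking"))
  qa <- quick_assign(act_rows)
  frA <- activity_features(qa$assigned,
                           split_on_boundaries(activity_episodes(act_rows),
                                               inst), inst)
  expect_equal(feature_value(frA, "rapids_activity_recognition_count"), 4)
  expect_identical(feature_value(frA,
                                 "rapids_activity_recognition_mostcommonactivity"),
                   "still")
  expect_equal(feature_value(frA,
                             "rapids_activity_recognition_countuniqueactivities"),
               2)

  kb <- quick_assign(data.table(
    timestamp = utc_ms("2020-01-01 09:00:00") + c(0, 500, 1000, 60000),
    package_name = "chat", before_text = c("", "h", "he", "hel"),
    current_text = c("h", "he", "hel", "hello")))
  fk <- keyboard_features(kb$assigned, kb$instances)
  expect_equal(feature_value(fk, "rapids_keyboard_sessioncount"), 2)
  expect_equal(feature_value(fk, "rapids_keyboard_totalkeyboardtouches"), 4)
  expect_equal(feature_value(fk, "rapids_keyboard_maxtextlength"), 5)
  expect_equal(feature_value(fk,
                             "rapids_keyboard_changeintextlengthmorethanone"),
               1)

  acc <- quick_assign(data.table(
    timestamp = utc_ms("2020-01-01 09:00:00") + (0:2) * 1000,
    double_values_0 = c(3, 0, 0), double_values_1 = c(4, 0, 5),
    double_values_2 = c(0, 12, 0)))
  fac <- accelerometer_features(acc$assigned, acc$instances)
  expect_equal(feature_value(fac, "rapids_accelerometer_maxmagnitude"), 12)
  expect_equal(feature_value(fac, "rapids_accelerometer_minmagnitude"), 5)
  expect_equal(feature_value(fac, "rapids_accelerometer_avgmagnitude"),
               mean(c(5, 12, 5)))
})

test_that("conversation features bin audio classes and voice runs", {
  rows <- data.table(
    timestamp = utc_ms("2020-01-01 09:00:00") + c(0:2, 10:11, 30) * 60000,
    inference = c(2L, 2L, 2L, 1L, 0L, 3L),
    double_energy = c(0.8, 0.9, 0.7, 0.4, 0.0, 0.1))
  qa <- quick_assign(rows)
  fr <- conversation_features(qa$assigned, qa$instances)
  expect_equal(feature_value(fr, "rapids_conversation_countconversation"), 1)
  expect_equal(feature_value(fr, "rapids_conversation_minutesvoice"), 3)
  expect_equal(feature_value(fr, "rapids_conversation_minutesnoise"), 1)
  expect_equal(feature_value(fr, "rapids_conversation_sumenergyvoice"),
               0.8 + 0.9 + 0.7)
  expect_equal(feature_value(fr, "rapids_conversation_voicesensedfraction"),
               3 / 6)
  expect_identical(sum(grepl("rapids_conversation", names(fr))), 30L)
})
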