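# Mobility: haversine, stationarity, clustering, the two location providers,
# and the circadian periodogram.

anchor_points <- function(n, lat, lon, jitter = 0, t0 = 0, step_ms = 60000) {
  data.table(timestamp = t0 + (0:(n - 1)) * step_ms,
             double_latitude = lat + rnorm(n, 0, jitter),
             double_longitude = lon + rnorm(n, 0, jitter))
}

test_that("haversine matches closed-form checks", {
  expect_equal(haversine_m(12.3, 45.6, 12.3, 45.6), 0)
  expect_equal(haversine_m(0, 0, 0, 180), pi * 6371000, tolerance = 1e-9)
  expect_equal(haversine_m(0, 0, 0.001, 0),
               6371000 * 0.001 * pi / 180, tolerance = 1e-6)
})

test_that("stationarity labeling follows the speed threshold", {
  p <- detect_stationary(anchor_points(5, 40, -80))
  expect_true(all(p$stationary))
  # ~1 km hops at 1-minute spacing: 60 km/h
  mov <- data.table(timestamp = (0:4) * 60000,
                    double_latitude = 40 + (0:4) * 0.009,
                    double_longitude = -80)
  pm <- detect_stationary(mov)
  expect_true(all(!pm$stationary[-1]))
  single <- detect_stationary(anchor_points(1, 40, -80))
  expect_true(single$stationary)
})

test_that("place clustering separates anchors and ranks by dwell", {
  set.seed(2)
  a <- anchor_points(10, 40.0, -80.0, 1e-5)
  b <- anchor_points(10, 40.045, -80.0, 1e-5, t0 = 10 * 60000) # ~5 km away
  cl <- cluster_places(rbind(a, b), eps_m = 100, min_samples = 5)
  expect_identical(nrow(cl$clusters), 2L)
  expect_identical(sort(unique(cl$points$cluster)), c(1L, 2L))
  # all identical -> one cluster
  one <- cluster_places(anchor_points(8, 40, -80))
  expect_identical(nrow(one$clusters), 1L)
  # below min_samples -> all noise
  none <- cluster_places(anchor_points(3, 40, -80), min_samples = 5)
  expect_identical(nrow(none$clusters), 0L)
  expect_true(all(none$points$cluster == 0L))
})

test_that("cluster provider: symmetric two-anchor day gives rog = D/2", {
  set.seed(8)
  t0 <- utc_ms("2020-01-01 00:00:00")
  half <- anchor_points(360, 40.0, -80.0, 0, t0 = t0, step_ms = 120000)
  half2 <- anchor_points(360, 40.0, -79.97, 0,
                         t0 = t0 + 360 * 120000, step_ms = 120000)
  pts <- rbind(half, half2)
  cl <- cluster_places(pts, 100, 5)
  inst <- daily_instances("2020-01-01")
  a <- assign_segments(localize_stream(cl$points, UTC_TZH), inst)
  fr <- cluster_provider_features(a, cl$clusters, inst)
  D <- haversine_m(40, -80, 40, -79.97)
  expect_equal(feature_value(fr, "doryab_locations_radiusgyration"), D / 2,
               tolerance = 0.02 * D)
  expect_equal(feature_value(fr, "doryab_locations_numberofsignificantplaces"),
               2)
  expect_equal(feature_value(fr, "doryab_locations_numberlocationtransitions"),
               1)
  # equal dwell -> maximal entropy ln 2, normalized 1
  expect_equal(feature_value(fr, "doryab_locations_locationentropy"), log(2),
               tolerance = 0.01)
  expect_equal(feature_value(fr, "doryab_locations_normalizedlocationentropy"),
               1, tolerance = 0.01)
})

test_that("single cluster: entropy 0, normalized NA; rog 0", {
  pts <- anchor_points(50, 40, -80, 0, t0 = utc_ms("2020-01-01 10:00:00"))
  cl <- cluster_places(pts, 100, 5)
  inst <- daily_instances("2020-01-01")
  a <- assign_segments(localize_stream(cl$points, UTC_TZH), inst)
  fr <- cluster_provider_features(a, cl$clusters, inst)
  expect_equal(feature_value(fr, "doryab_locations_locationentropy"), 0)
  expect_true(is.na(feature_value(fr,
                                  "doryab_locations_normalizedlocationentropy")))
  expect_equal(feature_value(fr, "doryab_locations_radiusgyration"), 0)
})

test_that("entropy bounds and translation invariance of rog", {
  set.seed(31)
  t0 <- utc_ms("2020-01-01 00:00:00")
  mk <- function(lat0, lon0) {
    rbind(anchor_points(200, lat0, lon0, 1e-5, t0 = t0, step_ms = 120000),
          anchor_points(140, lat0 + 0.02, lon0, 1e-5,
                        t0 = t0 + 200 * 120000, step_ms = 120000),
          anchor_points(80, lat0, lon0 + 0.03, 1e-5,
                        t0 = t0 + 340 * 120000, step_ms = 120000))
  }
  inst <- daily_instances("2020-01-01")
  vals <- lapply(list(c(40, -80), c(40.5, -80.5)), function(o) {
    cl <- cluster_places(mk(o[1], o[2]), 100, 5)
    a <- assign_segments(localize_stream(cl$points, UTC_TZH), inst)
    fr <- cluster_provider_features(a, cl$clusters, inst)
    k <- feature_value(fr, "doryab_locations_numberofsignificantplaces")
    h <- feature_value(fr, "doryab_locations_locationentropy")
    expect_gte(h, 0); expect_lte(h, log(k))
    nh <- feature_value(fr, "doryab_locations_normalizedlocationentropy")
    expect_gte(nh, 0); expect_lte(nh, 1)
    feature_value(fr, "doryab_locations_radiusgyration")
  })
  expect_equal(vals[[1]], vals[[2]], tolerance = 0.02 * vals[[1]])
})

test_that("circadian movement: 24h-periodic trace beats its shuffle", {
  set.seed(4)
  t0 <- utc_ms("2020-01-01 00:00:00")
  n <- 7 * 144   # 7 days at 10-min sampling
  ts <- t0 + (0:(n - 1)) * 600000
  lat <- 40 + 0.01 * sin(2 * pi * (ts - t0) / 8.64e7)
  lon <- -80 + 0.01 * cos(2 * pi * (ts - t0) / 8.64e7)
  per <- data.table(timestamp = ts, double_latitude = lat,
                    double_longitude = lon)
  shuf <- copy(per)[, `:=`(double_latitude = sample(lat),
                           double_longitude = sample(lon))]
  expect_gt(circadian_movement(per), circadian_movement(shuf))
})

test_that("trajectory provider: stationary-only day at home", {
  pts <- anchor_points(720, 40.0, -80.0, 1e-6,
                       t0 = utc_ms("2020-01-01 00:00:00"), step_ms = 120000)
  cl <- cluster_places(pts, 100, 5)
  inst <- daily_instances("2020-01-01")
  a <- assign_segments(localize_stream(
    detect_stationary(cl$points), UTC_TZH), inst)
  fr <- trajectory_provider_features(a, cl$clusters, inst)
  expect_equal(feature_value(fr, "barnett_locations_probpause"), 1)
  expect_equal(feature_value(fr, "barnett_locations_disttravelled"), 0)
  expect_equal(feature_value(fr, "barnett_locations_siglocsvisited"), 1)
  expect_gt(feature_value(fr, "barnett_locations_hometime"), 1400)
})

test_that("trajectory provider: two-anchor commute recovers geometry", {
  set.seed(9)
  t0 <- utc_ms("2020-01-01 00:00:00")
  lat0 <- 40; lon0 <- -80; lon1 <- -79.97
  D <- haversine_m(lat0, lon0, lat0, lon1)
  leg <- function(from, to, t_start, n) {
    data.table(timestamp = t_start + (0:(n - 1)) * 60000,
               double_latitude = lat0,
               double_longitude = from + (to - from) * (0:(n - 1)) / (n - 1))
  }
  pts <- rbind(
    anchor_points(480, lat0, lon0, 1e-6, t0 = t0, step_ms = 60000),
    leg(lon0, lon1, t0 + 480 * 60000, 15),
    anchor_points(480, lat0, lon1, 1e-6, t0 = t0 + 496 * 60000,
                  step_ms = 60000),
    leg(lon1, lon0, t0 + 976 * 60000, 15),
    anchor_points(440, lat0, lon0, 1e-6, t0 + 992 * 60000, step_ms = 60000))
  st <- detect_stationary(pts)
  cl <- cluster_places(st[st$stationary == TRUE], 100, 5)
  lab <- cl$points[, .(timestamp, cluster)]
  st2 <- lab[st, on = "timestamp"]
  st2[is.na(cluster), cluster := 0L]
  inst <- daily_instances("2020-01-01")
  a <- assign_segments(localize_stream(st2, UTC_TZH), inst)
  fr <- trajectory_provider_features(a, cl$clusters, inst)
  expect_equal(feature_value(fr, "barnett_locations_siglocsvisited"), 2)
  expect_equal(feature_value(fr, "barnett_locations_disttravelled"), 2 * D,
               tolerance = 0.05 * 2 * D)
  expect_equal(feature_value(fr, "barnett_locations_maxdiam"), D,
               tolerance = 0.05 * D)
  expect_gt(feature_value(fr, "barnett_locations_probpause"), 0.9)
  # no points in segment -> minsmissing = full segment
  inst2 <- daily_instances("2020-06-01")
  fr2 <- trajectory_provider_features(a[0], cl$clusters, inst2)
  expect_equal(feature_value(fr2, "barnett_locations_minsmissing"), 1440)
})

test_that("accuracy filter drops imprecise fixes", {
  p <- data.table(timestamp = 1:3 * 1000, double_latitude = 40,
                  double_longitude = -80, accuracy = c(10, 500, 50))
  expect_identical(nrow(filter_accuracy(p, 100)), 2L)
})
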