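# Seeded synthetic-study generator. The default profile is the package's
# reference world: 3 participants over 7 days (2020-03-04 to 2020-03-10),
# one living in America/New_York across the 2020-03-08 spring-forward
# transition (and carrying two phone devices, exercising device merging),
# one with a 12 h/day data dropout, and one two-anchor commuter with
# symmetric dwell at home and work. Every generated quantity is recorded in
# a ground-truth manifest so end-to-end recovery is checkable. Same profile
# + seed => byte-identical files.

#' Default synthetic study profile
#'
#' @param seed integer RNG seed
#' @param n_participants number of participants (default 3)
#' @param days study length in days (default 7)
#' @param start_date first study day (default 2020-03-04, so the default
#'   7-day window straddles a US DST spring-forward)
#' @param screen_sessions_per_day screen sessions per day (default 3)
#' @param screen_session_min session length, minutes (default 10)
#' @param calls_per_day mean calls per day (default 5)
#' @param battery_discharge_rate_per_h battery drain, percent/h (default 5)
#' @param hr_baseline,hr_amplitude circadian heart-rate model, bpm
#' @param step_bouts_per_day walking bouts per day (default 2)
#' @param step_bout_min bout length, minutes (default 30)
#' @param dropout_start_minute,dropout_pid daily missing window start
#'   (minutes since midnight; the window runs to midnight) for the dropout
#'   participant
#' @param anchor_distance_m planted home-work distance (default 3000 m)
#' @param location_interval_s GPS sampling interval (default 120 s)
#' @return a `synth_profile` list
#' @export
synth_profile <- function(seed = 1,
                          n_participants = 3,
                          days = 7,
                          start_date = as.Date("2020-03-04"),
                          screen_sessions_per_day = 3,
                          screen_session_min = 10,
                          calls_per_day = 5,
                          battery_discharge_rate_per_h = 5,
                          hr_baseline = 70,
                          hr_amplitude = 10,
                          step_bouts_per_day = 2,
                          step_bout_min = 30,
                          dropout_start_minute = 720,
                          dropout_pid = 2,
                          anchor_distance_m = 3000,
                          location_interval_s = 120) {
  structure(as.list(environment()), class = "synth_profile")
}

.pid_name <- function(i) sprintf("p%02d", i)

# wall-clock seconds-of-study -> UTC ms under a zone (gap -> boundary)
.wall_s_to_utc_ms <- function(day0_wall, offset_s, tz) {
  wall <- day0_wall + offset_s
  as.numeric(lubridate::force_tz(wall, tz, roll_dst = .ROLL_DST)) * 1000
}

.synth_tz <- function(profile, i) {
  if (i == 1) "America/New_York" else "UTC"
}

# per-(participant, stream) deterministic substream
.sub_seed <- function(seed, i, stream) {
  (seed * 1009L + i * 101L +
     sum(utf8ToInt(stream))) %% .Machine$integer.max
}

.drop_window <- function(profile, i, offset_s) {
  if (i != profile$dropout_pid) return(rep(FALSE, length(offset_s)))
  (offset_s %% 86400) >= profile$dropout_start_minute * 60
}

#' Generate a complete synthetic study directory
#'
#' Writes the participant registry, tz history, a daily segment file, a
#' runnable pipeline config, all raw stream CSVs in the dialects the loaders
#' read, and `ground_truth.json` recording every planted quantity.
#'
#' @param profile from [synth_profile()]
#' @param out_dir destination directory (created)
#' @return invisibly, the ground-truth manifest list
#' @export
generate_study <- function(profile = synth_profile(), out_dir) {
  dir.create(file.path(out_dir, "data"), recursive = TRUE,
             showWarnings = FALSE)
  days <- seq(profile$start_date, by = "day", length.out = profile$days)
  truth <- list(seed = profile$seed, days = profile$days,
                participants = list())
  reg <- list(); tzh <- list()
  for (i in seq_len(profile$n_participants)) {
    pid <- .pid_name(i)
    tz <- .synth_tz(profile, i)
    phone_ids <- if (i == 1) paste0(pid, "_phoneA;", pid, "_phoneB") else
      paste0(pid, "_phone")
    reg[[i]] <- data.table(
      pid = pid, phone_ids = phone_ids,
      fitbit_ids = paste0(pid, "_fitbit"),
      empatica_ids = paste0(pid, "_empatica"),
      platform = "android",
      start_date = as.character(days[1]),
      end_date = as.character(days[length(days)]))
    tzh[[i]] <- data.table(pid = pid, tz = tz, start_utc_ms = 0)
    truth$participants[[pid]] <- .generate_participant(profile, i, days,
                                                       out_dir)
  }
  fwrite(rbindlist(reg), file.path(out_dir, "participants.csv"))
  fwrite(rbindlist(tzh), file.path(out_dir, "tz_history.csv"))
  fwrite(data.table(label = "daily", kind = "periodic", length = "24h",
                    start_time = "00:00:00", repeat_type = "every_day",
                    repeat_value = "", shift = "0s", shift_direction = "after",
                    event_file = ""),
         file.path(out_dir, "segments.csv"))
  cfg <- list(
    study = list(name = "synthetic", registry = "participants.csv",
                 tz_history = "tz_history.csv", segments = "segments.csv",
                 data_root = "data", output_root = "output"),
    providers = stats::setNames(
      lapply(c("calls_incoming", "screen", "battery", "light", "data_yield",
               "locations", "fitbit_heartrate_intraday",
               "fitbit_steps_intraday", "fitbit_data_yield",
               "empatica_electrodermal_activity"),
             function(s) list(enabled = TRUE)),
      c("calls_incoming", "screen", "battery", "light", "data_yield",
        "locations", "fitbit_heartrate_intraday", "fitbit_steps_intraday",
        "fitbit_data_yield", "empatica_electrodermal_activity")),
    workers = 1, seed = profile$seed)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

.generate_participant <- function(profile, i, days, out_dir) {
  pid <- .pid_name(i)
  tz <- .synth_tz(profile, i)
  day0 <- as.POSIXct(paste(days[1], "00:00:00"), tz = "UTC")  # wall
  total_s <- profile$days * 86400
  phone_dev <- function(offset_s) {
    # participant 1 switches phones mid-study
    if (i == 1) {
      ifelse(offset_s < total_s / 2, paste0(pid, "_phoneA"),
             paste0(pid, "_phoneB"))
    } else rep(paste0(pid, "_phone"), length(offset_s))
  }
  dev_dirs <- unique(c(phone_dev(0), phone_dev(total_s - 1),
                       paste0(pid, "_fitbit"), paste0(pid, "_empatica")))
  for (d in dev_dirs) {
    dir.create(file.path(out_dir, "data", d), recursive = TRUE,
               showWarnings = FALSE)
  }
  write_stream <- function(dt, offset_s, sensor, device) {
    keep <- !.drop_window(profile, i, offset_s)
    dt <- dt[keep]
    device <- device[keep]
    for (dv in unique(device)) {
      f <- file.path(out_dir, "data", dv, paste0(sensor, ".csv"))
      fwrite(dt[device == dv][order(timestamp)], f)
    }
    sum(keep)
  }
  truth <- list(pid = pid, tz = tz)

  # -- screen: fixed daytime sessions --
  set.seed(.sub_seed(profile$seed, i, "screen"))
  sess_starts_min <- c(9 * 60, 14 * 60, 20 * 60)[seq_len(
    min(3, profile$screen_sessions_per_day))]
  if (profile$screen_sessions_per_day > 3) {
    sess_starts_min <- c(sess_starts_min,
                         sort(sample(setdiff(6:23 * 60, sess_starts_min),
                                     profile$screen_sessions_per_day - 3)))
  }
  off <- as.vector(outer(sess_starts_min * 60, (seq_along(days) - 1) * 86400,
                         "+"))
  off <- sort(off)
  ev_off <- as.vector(rbind(off, off + profile$screen_session_min * 60))
  scr <- data.table(timestamp = .wall_s_to_utc_ms(day0, ev_off, tz),
                    screen_status = rep(c(3L, 0L), length(off)))
  kept <- write_stream(scr, ev_off, "screen", phone_dev(ev_off))
  keep_mask <- !.drop_window(profile, i, off)
  truth$screen <- list(
    sessions_planted = length(off),
    sessions_surviving_dropout = sum(keep_mask &
                                       !.drop_window(profile, i,
                                                     off + profile$screen_session_min * 60)),
    session_minutes = profile$screen_session_min)

  # -- calls --
  set.seed(.sub_seed(profile$seed, i, "calls"))
  n_calls <- stats::rpois(profile$days, profile$calls_per_day)
  call_off <- unlist(lapply(seq_along(days), function(d) {
    sort(round(stats::runif(n_calls[d], 6 * 3600, 23 * 3600))) +
      (d - 1) * 86400
  }))
  calls <- data.table(
    timestamp = .wall_s_to_utc_ms(day0, call_off, tz),
    call_type = sample(c("incoming", "outgoing", "missed"),
                       length(call_off), replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)),
    call_duration = round(stats::rexp(length(call_off), 1 / 120)),
    trace = sample(paste0("contact", 1:5), length(call_off), replace = TRUE))
  calls[call_type == "missed", call_duration := 0]
  write_stream(calls, call_off, "calls", phone_dev(call_off))
  truth$calls <- list(planted = length(call_off),
                      surviving_dropout = sum(!.drop_window(profile, i,
                                                            call_off)))

  # -- battery: sawtooth discharge/charge, sample every 10 min --
  rate <- profile$battery_discharge_rate_per_h
  boff <- seq(0, total_s - 1, by = 600)
  tod_h <- (boff %% 86400) / 3600
  level <- ifelse(tod_h < 16, pmax(0, 100 - rate * tod_h),
                  pmin(100, (100 - rate * 16) + 20 * (tod_h - 16)))
  bat <- data.table(timestamp = .wall_s_to_utc_ms(day0, boff, tz),
                    battery_level = round(level))
  write_stream(bat, boff, "battery", phone_dev(boff))
  truth$battery <- list(discharge_rate_per_h = rate)

  # -- light: 5-min samples, day/night lognormal --
  set.seed(.sub_seed(profile$seed, i, "light"))
  loff <- seq(0, total_s - 1, by = 300)
  is_day <- (loff %% 86400) >= 7 * 3600 & (loff %% 86400) < 20 * 3600
  lux <- round(exp(stats::rnorm(length(loff), ifelse(is_day, 5.5, 1), 0.6)), 1)
  light <- data.table(timestamp = .wall_s_to_utc_ms(day0, loff, tz),
                      double_light_lux = lux)
  write_stream(light, loff, "light", phone_dev(loff))

  # -- locations --
  set.seed(.sub_seed(profile$seed, i, "locations"))
  home <- c(lat = 40.4406, lon = -79.9959)
  # anchor_distance_m due east
  dlon <- profile$anchor_distance_m /
    (.EARTH_RADIUS_M * cos(home[["lat"]] * pi / 180)) * 180 / pi
  work <- c(lat = home[["lat"]], lon = home[["lon"]] + dlon)
  goff <- seq(0, total_s - 1, by = profile$location_interval_s)
  tod <- goff %% 86400
  commuter <- (i == 3)
  frac <- pmin(1, pmax(0, ifelse(tod < 42300, 0,            # at home till 11:45
                                 ifelse(tod < 43200, (tod - 42300) / 900, # out
                                        ifelse(tod < 85500, 1,            # work
                                               1 - (tod - 85500) / 900)))))
  if (!commuter) frac <- rep(0, length(goff))
  jit <- 1e-5   # ~1 m gps noise
  lat <- home[["lat"]] + frac * (work[["lat"]] - home[["lat"]]) +
    stats::rnorm(length(goff), 0, jit)
  lon <- home[["lon"]] + frac * (work[["lon"]] - home[["lon"]]) +
    stats::rnorm(length(goff), 0, jit)
  gps <- data.table(timestamp = .wall_s_to_utc_ms(day0, goff, tz),
                    double_latitude = round(lat, 7),
                    double_longitude = round(lon, 7),
                    accuracy = round(stats::runif(length(goff), 5, 30)))
  write_stream(gps, goff, "locations", phone_dev(goff))
  truth$locations <- list(
    home = as.list(home), work = if (commuter) as.list(work) else NULL,
    n_anchors = if (commuter) 2L else 1L,
    anchor_distance_m = if (commuter)
      haversine_m(home[["lat"]], home[["lon"]], work[["lat"]], work[["lon"]])
    else 0,
    dwell_minutes_home_per_day = if (commuter) (42300 + 900) / 60 else 1440,
    dwell_minutes_work_per_day = if (commuter) (85500 - 43200) / 60 else 0)

  # -- fitbit heart rate: per-minute circadian sinusoid --
  set.seed(.sub_seed(profile$seed, i, "hr"))
  hoff <- seq(0, total_s - 1, by = 60)
  hr <- profile$hr_baseline +
    profile$hr_amplitude * sin(2 * pi * ((hoff %% 86400) / 3600 - 6) / 24) +
    stats::rnorm(length(hoff), 0, 2)
  hrdt <- data.table(timestamp = .wall_s_to_utc_ms(day0, hoff, tz),
                     heartrate = round(pmax(40, hr)))
  write_stream(hrdt, hoff, "fitbit_heartrate_intraday",
               rep(paste0(pid, "_fitbit"), length(hoff)))
  truth$heart_rate <- list(baseline = profile$hr_baseline,
                           amplitude = profile$hr_amplitude)

  # -- fitbit steps: walking bouts over a sedentary day --
  set.seed(.sub_seed(profile$seed, i, "steps"))
  bout_starts_min <- c(9 * 60 + 30, 18 * 60)[seq_len(
    min(2, profile$step_bouts_per_day))]
  soff <- hoff
  tod_min <- (soff %% 86400) / 60
  in_bout <- rep(FALSE, length(soff))
  for (b in bout_starts_min) {
    in_bout <- in_bout | (tod_min >= b & tod_min < b + profile$step_bout_min)
  }
  steps <- ifelse(in_bout, 80 + round(stats::rnorm(length(soff), 20, 5)), 0)
  stepdt <- data.table(timestamp = .wall_s_to_utc_ms(day0, soff, tz),
                       steps = pmax(0, steps))
  write_stream(stepdt, soff, "fitbit_steps_intraday",
               rep(paste0(pid, "_fitbit"), length(soff)))
  truth$steps <- list(bouts_per_day = length(bout_starts_min),
                      bout_minutes = profile$step_bout_min)

  # -- empatica EDA: per-minute noisy tonic level --
  set.seed(.sub_seed(profile$seed, i, "eda"))
  eda <- round(2 + 0.5 * sin(2 * pi * (hoff %% 86400) / 86400) +
                 abs(stats::rnorm(length(hoff), 0, 0.3)), 3)
  edadt <- data.table(timestamp = .wall_s_to_utc_ms(day0, hoff, tz),
                      electrodermal_activity = eda)
  write_stream(edadt, hoff, "empatica_electrodermal_activity",
               rep(paste0(pid, "_empatica"), length(hoff)))

  # planted data yield: phone streams cover every minute via light/battery?
  # light samples every 5 min -> not every minute. HR covers every minute on
  # the fitbit side. Phone per-minute yield is dominated by 5-min light
  # sampling: 1 sampled minute per 5 -> ratio 0.2 without dropout. Record
  # the exact expectation from what was planted instead:
  truth$yield <- list(
    dropout = (i == profile$dropout_pid),
    expected_fitbit_minute_ratio = if (i == profile$dropout_pid)
      profile$dropout_start_minute / 1440 else 1)
  truth
}
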