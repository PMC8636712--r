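# Fitbit and Empatica feature providers.
#
# Input dialect: flattened per-stream CSVs (one row per sample or per daily
# summary record), not raw vendor JSON. Summary providers are meant for
# multi-day periodic segments; intraday providers run on any segment.

# nine value statistics shared by Empatica streams and HR intraday:
# max/min/avg/median/mode/std + difference of max/min from the mode +
# Shannon entropy (natural log) over the empirical distribution of values
# rounded to `round_digits` decimals.
.value_stats9 <- function(v, stem, round_digits = 2) {
  v <- as.numeric(v)   # keep group-wise result types stable (median!)
  mode_v <- .mode_min(round(v, round_digits))
  out <- list(max(v), min(v), mean(v), median(v), mode_v, .sd_or_na(v),
              max(v) - mode_v, min(v) - mode_v,
              .shannon(as.numeric(table(round(v, round_digits)))))
  names(out) <- paste0(c("max", "min", "avg", "median", "mode", "std",
                         "diffmaxmode", "diffminmode", "entropy"), stem)
  out
}

.EMPATICA_VALUE <- list(
  empatica_heartrate = c(col = "heartrate", stem = "hr"),
  empatica_temperature = c(col = "temperature", stem = "temp"),
  empatica_electrodermal_activity = c(col = "electrodermal_activity",
                                      stem = "eda"),
  empatica_blood_volume_pulse = c(col = "blood_volume_pulse", stem = "bvp"),
  empatica_inter_beat_interval = c(col = "inter_beat_interval", stem = "ibi"))

#' Empatica stream features (9 value statistics per segment)
#'
#' Applies to heart rate, skin temperature, electrodermal activity, blood
#' volume pulse, and inter-beat interval streams. The accelerometer stream
#' uses the 5 magnitude statistics instead (see
#' [accelerometer_features()] with `sensor = "empatica_accelerometer"`).
#' IBI samples are used at their event times as-is; no interpolation.
#'
#' @param assigned assigned samples
#' @param instances instance table
#' @param sensor one of the five scalar Empatica stream names
#' @param round_digits decimals for entropy discretization (default 2)
#' @export
empatica_stream_features <- function(assigned, instances, sensor,
                                     round_digits = 2) {
  spec <- .EMPATICA_VALUE[[sensor]]
  if (is.null(spec)) .stopf("not a scalar empatica stream: '%s'", sensor)
  stats <- if (nrow(assigned)) assigned[, {
    v <- suppressWarnings(as.numeric(get(spec[["col"]])))
    v <- v[is.finite(v)]
    if (length(v)) .value_stats9(v, spec[["stem"]], round_digits) else NULL
  }, by = instance_id] else NULL
  .emit_features(instances, stats, sensor, "rapids")
}

#' Heart-rate zone boundaries
#' @param boundaries three strictly ascending cut-points (bpm) separating
#'   out-of-range / fat-burn / cardio / peak zones
#' @return validated numeric vector
#' @export
heart_rate_zones <- function(boundaries = c(90, 120, 160)) {
  if (length(boundaries) != 3 || is.unsorted(boundaries, strictly = TRUE)) {
    .stopf("heart-rate zones need 3 strictly ascending cut-points")
  }
  boundaries
}

#' Fitbit intraday heart-rate features (13)
#'
#' The nine value statistics plus minutes in each of the four zones; each
#' per-minute sample contributes one minute to its zone.
#' @param assigned assigned per-minute samples (heartrate)
#' @param instances instance table
#' @param zones output of [heart_rate_zones()]
#' @export
heart_rate_intraday_features <- function(assigned, instances,
                                         zones = heart_rate_zones()) {
  zones <- heart_rate_zones(zones)
  stats <- if (nrow(assigned)) assigned[, {
    v <- heartrate
    zi <- findInterval(v, zones)   # 0..3
    c(.value_stats9(v, "hr"),
      list(minutesonoutofrangezone = as.numeric(sum(zi == 0)),
           minutesonfatburnzone = as.numeric(sum(zi == 1)),
           minutesoncardiozone = as.numeric(sum(zi == 2)),
           minutesonpeakzone = as.numeric(sum(zi == 3))))
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "fitbit_heartrate_intraday", "rapids",
                 zero_fill = paste0("minuteson",
                                    c("outofrange", "fatburn", "cardio",
                                      "peak"), "zone"))
}

# run-length bouts over sampled minutes; a sampling gap > 1 min breaks a run
.minute_bouts <- function(minute_idx, active) {
  o <- order(minute_idx)
  m <- minute_idx[o]; a <- active[o]
  brk <- c(TRUE, diff(m) > 1 | a[-1] != head(a, -1))
  g <- cumsum(brk)
  data.table(active = as.logical(tapply(a, g, function(x) x[1])),
             duration = as.numeric(tapply(m, g, length)))
}

.bout_stats <- function(d, suffix) {
  out <- if (length(d)) {
    list(as.numeric(length(d)), sum(d), max(d), min(d), mean(d), .sd_or_na(d))
  } else {
    list(0, 0, NA_real_, NA_real_, NA_real_, NA_real_)
  }
  names(out) <- paste0(c("countepisode", "sumduration", "maxduration",
                         "minduration", "avgduration", "stdduration"), suffix)
  out
}

#' Fitbit intraday steps features (17)
#'
#' Step-count statistics plus sedentary/active bout statistics: a sampled
#' minute is active when its step count reaches `sedentary_threshold`
#' (default 10); bouts are maximal runs of consecutive sampled minutes of
#' one state, broken by sampling gaps.
#' @param assigned assigned per-minute samples (steps)
#' @param instances instance table
#' @param sedentary_threshold steps/min at or above which a minute is active
#' @export
steps_intraday_features <- function(assigned, instances,
                                    sedentary_threshold = 10) {
  stats <- if (nrow(assigned)) assigned[, {
    minute <- floor(timestamp / 60000)
    bouts <- .minute_bouts(minute, steps >= sedentary_threshold)
    c(list(sumsteps = sum(steps), maxsteps = as.numeric(max(steps)),
           minsteps = as.numeric(min(steps)), avgsteps = mean(steps),
           stdsteps = .sd_or_na(steps)),
      .bout_stats(bouts$duration[!bouts$active], "sedentarybout"),
      .bout_stats(bouts$duration[bouts$active], "activebout"))
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "fitbit_steps_intraday", "rapids",
                 zero_fill = c("sumsteps", "countepisodesedentarybout",
                               "sumdurationsedentarybout",
                               "countepisodeactivebout",
                               "sumdurationactivebout"))
}

#' Fitbit steps summary features (5, multi-day segments)
#'
#' max/min/avg/median/std of the daily step totals falling in the segment.
#' @param assigned assigned daily summary rows (steps)
#' @param instances instance table
#' @export
steps_summary_features <- function(assigned, instances) {
  stats <- if (nrow(assigned)) assigned[, {
    v <- as.numeric(steps)
    list(maxsumsteps = max(v), minsumsteps = min(v), avgsumsteps = mean(v),
         mediansumsteps = median(v), stdsumsteps = .sd_or_na(v))
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "fitbit_steps_summary", "rapids")
}

#' Fitbit heart-rate summary features (37, multi-day segments)
#'
#' Nine statistics of daily resting heart rate plus, per zone, the
#' sum/max/min/avg/std of daily zone minutes and sum/avg of daily zone
#' calories.
#' @param assigned assigned daily summary rows
#' @param instances instance table
#' @export
heartrate_summary_features <- function(assigned, instances) {
  zones <- c("outofrange", "fatburn", "cardio", "peak")
  stats <- if (nrow(assigned)) assigned[, {
    out <- .value_stats9(as.numeric(heartrate_daily_restinghr), "restinghr")
    for (z in zones) {
      m <- as.numeric(get(paste0("heartrate_", z, "_minutes")))
      k <- as.numeric(get(paste0("heartrate_", z, "_calories")))
      o <- list(sum(m), max(m), min(m), mean(m), .sd_or_na(m), sum(k), mean(k))
      names(o) <- paste0(c("summinutes", "maxminutes", "minminutes",
                           "avgminutes", "stdminutes", "sumcalories",
                           "avgcalories"), z, "zone")
      out <- c(out, o)
    }
    out
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "fitbit_heartrate_summary", "rapids",
                 zero_fill = as.vector(outer(c("summinutes", "sumcalories"),
                                             paste0(zones, "zone"), paste0)))
}

#' Fitbit intraday calories features (22)
#'
#' Per activity level (sedentary / lightly / fairly / very active): sampled
#' minutes, kcal, episode count and max/avg episode duration; plus total
#' kcal and mean kcal per sampled minute.
#' @param assigned assigned per-minute rows (calories, level)
#' @param instances instance table
#' @export
calories_intraday_features <- function(assigned, instances) {
  levels <- c("sedentary", "lightlyactive", "fairlyactive", "veryactive")
  stats <- if (nrow(assigned)) assigned[, {
    minute <- floor(timestamp / 60000)
    out <- list()
    o <- order(minute)
    lv <- as.character(level)[o]; mm <- minute[o]
    brk <- c(TRUE, diff(mm) > 1 | lv[-1] != head(lv, -1))
    g <- cumsum(brk)
    ep <- data.table(lv = tapply(lv, g, function(x) x[1]),
                     dur = as.numeric(tapply(mm, g, length)))
    for (l in levels) {
      sel <- as.character(level) == l
      d <- ep$dur[ep$lv == l]
      o2 <- list(as.numeric(sum(sel)), sum(calories[sel]),
                 as.numeric(length(d)),
                 if (length(d)) max(d) else NA_real_,
                 if (length(d)) mean(d) else NA_real_)
      names(o2) <- paste0(c("minutes", "calories", "countepisode",
                            "maxdurationepisode", "avgdurationepisode"), l)
      out <- c(out, o2)
    }
    out$sumcalories <- sum(calories)
    out$avgcaloriesperminute <- mean(calories)
    out
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "fitbit_calories_intraday", "rapids",
                 zero_fill = c(as.vector(outer(c("minutes", "calories",
                                                 "countepisode"),
                                               levels, paste0)),
                               "sumcalories"))
}

#' Fitbit sleep summary features (36, multi-day segments)
#'
#' Twelve statistics for each of the main-sleep, nap, and combined episode
#' sets. Bed/wake times are minutes since local midnight of the episode's
#' start/end.
#' @param assigned assigned daily summary rows (type, duration_ms,
#'   minutes_asleep, minutes_awake, efficiency, local_minute)
#' @param instances instance table
#' @export
sleep_summary_features <- function(assigned, instances) {
  stats <- if (nrow(assigned)) assigned[, {
    out <- list()
    for (ty in c("main", "nap", "all")) {
      r <- if (ty == "all") .SD else .SD[type == ty]
      o <- if (nrow(r)) {
        asleep <- as.numeric(r$minutes_asleep)
        wake_minute <- (r$local_minute +
                          as.numeric(r$duration_ms) / 60000) %% 1440
        list(as.numeric(nrow(r)), sum(as.numeric(r$duration_ms)) / 60000,
             sum(asleep), sum(as.numeric(r$minutes_awake)),
             mean(as.numeric(r$efficiency)), max(asleep), min(asleep),
             mean(asleep), .sd_or_na(asleep),
             mean(as.numeric(r$minutes_awake)),
             r$local_minute[which.min(r$timestamp)],
             wake_minute[which.max(r$timestamp)])
      } else {
        c(list(0, 0, 0, 0), rep(list(NA_real_), 8))
      }
      names(o) <- paste0(c("countepisode", "sumdurationinbed",
                           "sumdurationasleep", "sumdurationawake",
                           "avgefficiency", "maxdurationasleep",
                           "mindurationasleep", "avgdurationasleep",
                           "stddurationasleep", "avgdurationawake",
                           "firstbedtime", "lastwaketime"), ty)
      out <- c(out, o)
    }
    out
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "fitbit_sleep_summary", "rapids",
                 zero_fill = as.vector(outer(c("countepisode",
                                               "sumdurationinbed",
                                               "sumdurationasleep",
                                               "sumdurationawake"),
                                             c("main", "nap", "all"), paste0)))
}

#' Fitbit intraday sleep features, stage provider (21)
#'
#' Episode count, total/max/avg duration (minutes) per unified stage
#' (awake, light, deep, rem, classic asleep) over stage-episode fragments,
#' plus the asleep-to-in-bed ratio.
#' @param fragments sleep episode fragments from [split_on_boundaries()]
#' @param instances instance table
#' @export
sleep_intraday_features <- function(fragments, instances) {
  stages <- c("awake", "light", "deep", "rem", "asleep")
  stats <- if (nrow(fragments)) fragments[, {
    out <- list()
    for (s in stages) {
      d <- frag_minutes[stage == s]
      o <- list(as.numeric(length(d)), sum(d),
                if (length(d)) max(d) else NA_real_,
                if (length(d)) mean(d) else NA_real_)
      names(o) <- paste0(c("countepisode", "sumduration", "maxduration",
                           "avgduration"), s)
      out <- c(out, o)
    }
    tot <- sum(frag_minutes)
    out$ratioasleepinbed <- if (tot > 0)
      sum(frag_minutes[stage != "awake"]) / tot else NA_real_
    out
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "fitbit_sleep_intraday", "rapids",
                 zero_fill = as.vector(outer(c("countepisode", "sumduration"),
                                             stages, paste0)))
}

#' Fitbit intraday sleep features, aggregate provider (13)
#'
#' Duration statistics over all stage fragments, per-stage in-bed ratios,
#' bed/wake clock times, and the number of local dates with any sleep.
#' Clock times are derived from the segment's wall-clock start plus elapsed
#' time (a DST transition inside one sleep bout shifts them by the offset
#' change; see the vignette).
#' @inheritParams sleep_intraday_features
#' @export
sleep_intraday_price_features <- function(fragments, instances) {
  stats <- if (nrow(fragments)) fragments[, {
    d <- frag_minutes
    tot <- sum(d)
    wall0 <- seg_start_wall[1]
    first_wall <- wall0 + (min(frag_start_utc_ms) - seg_start_utc_ms[1]) / 1000
    last_wall <- wall0 + (max(frag_end_utc_ms) - seg_start_utc_ms[1]) / 1000
    ratios <- lapply(c("awake", "light", "deep", "rem"), function(s) {
      if (tot > 0) sum(d[stage == s]) / tot else NA_real_
    })
    names(ratios) <- paste0("ratio", c("awake", "light", "deep", "rem"),
                            "inbed")
    c(.bout_stats(d, "all"), ratios,
      list(firstbedtime = .minutes_since_midnight(first_wall),
           lastwaketime = .minutes_since_midnight(last_wall),
           countdaysleep = as.numeric(data.table::uniqueN(
             as.Date(lubridate::floor_date(
               wall0 + (frag_start_utc_ms - seg_start_utc_ms[1]) / 1000,
               "day"))))))
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "fitbit_sleep_intraday", "price",
                 zero_fill = c("countepisodeall", "sumdurationall",
                               "countdaysleep"))
}
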