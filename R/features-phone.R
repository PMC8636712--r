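# Smartphone feature providers (all phone sensors except locations).
#
# Shared contract: every provider receives rows already assigned to segment
# instances (assign_segments) or episode fragments (split_on_boundaries) plus
# the full instance table, and returns one FeatureRow per instance. Feature
# names are validated against the catalog, then globally qualified as
# provider_sensor_feature. Missing-data policy: a segment with zero rows gets
# count-like features 0 and statistic-like features NA (config can drop such
# rows downstream). All std are sample standard deviations (NA for n < 2);
# mode ties break to the smallest value; time-of-day features are minutes
# since local midnight.

.instance_skeleton <- function(instances) {
  as.data.table(instances)[, .(pid, label, instance_id,
                               seg_start_wall = start_wall,
                               seg_end_wall = end_wall,
                               seg_start_utc_ms = start_utc_ms,
                               seg_end_utc_ms = end_utc_ms)]
}

# stats: data.table keyed by instance_id with unqualified feature columns.
.emit_features <- function(instances, stats, sensor, provider,
                           zero_fill = character(0)) {
  expected <- provider_features(sensor, provider)
  skel <- .instance_skeleton(instances)
  out <- if (!is.null(stats) && nrow(stats)) {
    stats[skel, on = "instance_id"]
  } else {
    sk <- copy(skel)
    for (f in expected) sk[, (f) := NA_real_]
    sk
  }
  for (f in setdiff(expected, names(out))) out[, (f) := NA_real_]
  for (f in intersect(zero_fill, expected)) {
    v <- out[[f]]
    v[is.na(v)] <- 0
    out[, (f) := v]
  }
  meta <- c("pid", "label", "instance_id", "seg_start_wall", "seg_end_wall",
            "seg_start_utc_ms", "seg_end_utc_ms")
  out <- out[, c(meta, expected), with = FALSE]
  setnames(out, expected, paste(provider, sensor, expected, sep = "_"))
  setorder(out, pid, instance_id)
  out[]
}

#' Call features (incoming, outgoing, or missed)
#'
#' Incoming/outgoing (12 features): count, distinct contacts, duration
#' mean/sum/min/max/sd/mode, Shannon entropy of durations (natural log,
#' weights d_i / sum d; 0 when the total is 0 or n <= 1), time of first and
#' last call (minutes since local midnight), and the number of calls with the
#' most frequent contact. Missed (5): the non-duration subset.
#'
#' @param assigned call rows assigned to instances (needs call_type,
#'   call_duration seconds, trace, local_minute)
#' @param instances segment instance table
#' @param call_type "incoming", "outgoing", or "missed"
#' @return FeatureRow table, one row per instance
#' @export
call_features <- function(assigned, instances, call_type) {
  ctype <- call_type   # keep out of data.table scoping
  sensor <- paste0("calls_", ctype)
  rows <- assigned[assigned$call_type == ctype]
  if (nrow(rows) && any(rows$call_duration < 0, na.rm = TRUE)) {
    .warnf("calls: rejecting %d row(s) with negative duration",
           sum(rows$call_duration < 0, na.rm = TRUE))
    rows <- rows[call_duration >= 0]
  }
  stats <- if (nrow(rows)) rows[, {
    base <- list(
      count = as.numeric(.N),
      distinctcontacts = as.numeric(data.table::uniqueN(trace)),
      timefirstcall = local_minute[which.min(timestamp)],
      timelastcall = local_minute[which.max(timestamp)],
      countmostfrequentcontact = as.numeric(max(table(trace))))
    if (ctype != "missed") {
      d <- call_duration
      base <- c(base, list(
        meanduration = mean(d), sumduration = sum(d), minduration = min(d),
        maxduration = max(d), stdduration = .sd_or_na(d),
        modeduration = .mode_min(d), entropyduration = .shannon(d)))
    }
    base
  }, by = instance_id] else NULL
  .emit_features(instances, stats, sensor, "rapids",
                 zero_fill = c("count", "distinctcontacts",
                               "countmostfrequentcontact"))
}

#' SMS features (sent and received, 5 each)
#' @inheritParams call_features
#' @export
sms_features <- function(assigned, instances) {
  stats <- if (nrow(assigned)) assigned[, {
    out <- list()
    for (k in c("sent", "received")) {
      r <- .SD[message_type == k]
      out[[paste0("count", k)]] <- as.numeric(nrow(r))
      out[[paste0("distinctcontacts", k)]] <-
        if (nrow(r)) as.numeric(data.table::uniqueN(r$trace)) else 0
      out[[paste0("timefirstsms", k)]] <-
        if (nrow(r)) r$local_minute[which.min(r$timestamp)] else NA_real_
      out[[paste0("timelastsms", k)]] <-
        if (nrow(r)) r$local_minute[which.max(r$timestamp)] else NA_real_
      out[[paste0("countmostfrequentcontact", k)]] <-
        if (nrow(r)) as.numeric(max(table(r$trace))) else 0
    }
    out
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "sms", "rapids",
                 zero_fill = c(t(outer(c("count", "distinctcontacts",
                                         "countmostfrequentcontact"),
                                       c("sent", "received"), paste0))))
}

#' Screen features over episode fragments
#'
#' 7 features: episode count, duration sum/max/min/avg/sd (minutes), and
#' minutes from segment start to the first fragment start.
#' @param fragments screen fragments from [split_on_boundaries()]
#' @param instances instance table
#' @export
screen_features <- function(fragments, instances) {
  stats <- if (nrow(fragments)) fragments[, .(
    countepisode = as.numeric(.N),
    sumduration = sum(frag_minutes), maxduration = max(frag_minutes),
    minduration = min(frag_minutes), avgduration = mean(frag_minutes),
    stdduration = .sd_or_na(frag_minutes),
    firstuseafter = (min(frag_start_utc_ms) - seg_start_utc_ms[1]) / 60000
  ), by = instance_id] else NULL
  .emit_features(instances, stats, "screen", "rapids",
                 zero_fill = c("countepisode", "sumduration"))
}

#' Generic numeric-column features (light sensor)
#'
#' count, max, min, avg, median, std of the value column within the segment.
#' @param assigned assigned rows
#' @param instances instance table
#' @param sensor sensor name ("light")
#' @param value_column numeric column ("double_light_lux")
#' @param stem feature-name stem ("lux")
#' @export
generic_numeric_features <- function(assigned, instances, sensor = "light",
                                     value_column = "double_light_lux",
                                     stem = "lux") {
  rows <- copy(assigned)
  if (nrow(rows)) {
    v <- rows[[value_column]]
    if (!is.numeric(v)) {
      suppressWarnings(v <- as.numeric(v))
      if (any(is.na(v))) .warnf("%s: rejecting %d non-numeric row(s)",
                                sensor, sum(is.na(v)))
      rows <- rows[!is.na(v)]
      rows[, (value_column) := v[!is.na(v)]]
    }
  }
  stats <- if (nrow(rows)) rows[, {
    v <- as.numeric(get(value_column))
    stats::setNames(
      list(as.numeric(.N), max(v), min(v), mean(v), median(v), .sd_or_na(v)),
      c("count", paste0(c("max", "min", "avg", "median", "std"), stem)))
  }, by = instance_id] else NULL
  .emit_features(instances, stats, sensor, "rapids", zero_fill = "count")
}

#' Battery features over charge/discharge episode fragments
#' @param fragments battery fragments (kind, frag_minutes, rate_per_h)
#' @param instances instance table
#' @export
battery_features <- function(fragments, instances) {
  stats <- if (nrow(fragments)) fragments[, {
    d <- .SD[kind == "battery_discharge"]
    c <- .SD[kind == "battery_charge"]
    list(countdischarge = as.numeric(nrow(d)),
         sumdurationdischarge = sum(d$frag_minutes),
         countcharge = as.numeric(nrow(c)),
         sumdurationcharge = sum(c$frag_minutes),
         avgconsumptionrate = if (nrow(d)) mean(d$rate_per_h) else NA_real_,
         maxconsumptionrate = if (nrow(d)) max(d$rate_per_h) else NA_real_)
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "battery", "rapids",
                 zero_fill = c("countdischarge", "sumdurationdischarge",
                               "countcharge", "sumdurationcharge"))
}

#' Activity-recognition features
#'
#' count of rows, most common activity class, number of unique classes, and
#' minutes in stationary/mobile/vehicle bouts (from activity episodes split
#' at segment boundaries).
#' @param assigned assigned activity rows
#' @param fragments activity episode fragments
#' @param instances instance table
#' @export
activity_features <- function(assigned, fragments, instances) {
  stats <- if (nrow(assigned)) assigned[, .(
    count = as.numeric(.N),
    mostcommonactivity = as.character(.mode_min(as.character(activity_type))),
    countuniqueactivities = as.numeric(data.table::uniqueN(activity_type))
  ), by = instance_id] else NULL
  durs <- if (nrow(fragments)) {
    d <- fragments[, .(mins = sum(frag_minutes)),
                   by = .(instance_id, activity_class)]
    data.table::dcast(d, instance_id ~ activity_class, value.var = "mins",
                      fill = 0)
  } else NULL
  if (!is.null(durs)) {
    for (cl in c("stationary", "mobile", "vehicle")) {
      if (!cl %in% names(durs)) durs[, (cl) := 0]
    }
    setnames(durs, c("stationary", "mobile", "vehicle"),
             paste0("duration", c("stationary", "mobile", "vehicle")))
    stats <- if (is.null(stats)) durs else durs[stats, on = "instance_id"]
  }
  .emit_features(instances, stats, "activity_recognition", "rapids",
                 zero_fill = c("count", "countuniqueactivities",
                               paste0("duration",
                                      c("stationary", "mobile", "vehicle"))))
}

#' Foreground-application features
#' @param assigned assigned app rows (package_name, application_name)
#' @param instances instance table
#' @export
app_foreground_features <- function(assigned, instances) {
  stats <- if (nrow(assigned)) assigned[, .(
    count = as.numeric(.N),
    timeoffirstuse = local_minute[which.min(timestamp)],
    timeoflastuse = local_minute[which.max(timestamp)],
    frequencyentropy = .shannon(as.numeric(table(package_name)))
  ), by = instance_id] else NULL
  .emit_features(instances, stats, "applications_foreground", "rapids",
                 zero_fill = "count")
}

.scan_features3 <- function(assigned, instances, sensor, addr_col) {
  stats <- if (nrow(assigned)) assigned[, {
    tab <- table(get(addr_col))
    list(countscans = as.numeric(.N),
         uniquedevices = as.numeric(length(tab)),
         countscansmostuniquedevice = as.numeric(max(tab)))
  }, by = instance_id] else NULL
  .emit_features(instances, stats, sensor, "rapids",
                 zero_fill = c("countscans", "uniquedevices",
                               "countscansmostuniquedevice"))
}

#' Wi-Fi scan features (connected or visible access points)
#' @param assigned assigned rows
#' @param instances instance table
#' @param sensor "wifi_connected" or "wifi_visible"
#' @export
wifi_features <- function(assigned, instances, sensor = "wifi_connected") {
  addr <- if (sensor == "wifi_connected") "mac_address" else "bssid"
  .scan_features3(assigned, instances, sensor, addr)
}

#' Basic Bluetooth scan features
#' @inheritParams app_foreground_features
#' @export
bluetooth_features <- function(assigned, instances) {
  .scan_features3(assigned, instances, "bluetooth", "bt_address")
}

#' Extended Bluetooth features with device-ownership classes
#'
#' 9 scan statistics for each of three device classes: all scanned devices,
#' the participant's own devices, and others' devices. Ownership is inferred
#' by scan-frequency thresholding over the participant's whole input: a
#' device is "own" when its total scan count reaches `own_share` (default
#' 0.5) of the most-scanned device's count.
#'
#' @param assigned assigned bluetooth rows
#' @param instances instance table
#' @param own_share ownership threshold in (0, 1]
#' @export
bluetooth_doryab_features <- function(assigned, instances, own_share = 0.5) {
  own_set <- character(0)
  if (nrow(assigned)) {
    totals <- table(assigned$bt_address)
    own_set <- names(totals)[totals >= own_share * max(totals)]
  }
  stat9 <- function(r) {
    if (!nrow(r)) {
      return(list(countscans = 0, uniquedevices = 0, meanscans = NA_real_,
                  stdscans = NA_real_, modescans = NA_real_,
                  maxscans = NA_real_, minscans = NA_real_,
                  countscansmostfrequentdevice = 0,
                  countscansleastfrequentdevice = 0))
    }
    tab <- as.numeric(table(r$bt_address))
    list(countscans = as.numeric(nrow(r)),
         uniquedevices = as.numeric(length(tab)),
         meanscans = mean(tab), stdscans = .sd_or_na(tab),
         modescans = .mode_min(tab), maxscans = max(tab), minscans = min(tab),
         countscansmostfrequentdevice = max(tab),
         countscansleastfrequentdevice = min(tab))
  }
  stats <- if (nrow(assigned)) assigned[, {
    out <- list()
    for (cls in c("all", "own", "others")) {
      r <- switch(cls, all = .SD, own = .SD[bt_address %in% own_set],
                  others = .SD[!bt_address %in% own_set])
      s <- stat9(r)
      names(s) <- paste0(names(s), cls)
      out <- c(out, s)
    }
    out
  }, by = instance_id] else NULL
  zf <- as.vector(t(outer(c("countscans", "uniquedevices",
                            "countscansmostfrequentdevice",
                            "countscansleastfrequentdevice"),
                          c("all", "own", "others"), paste0)))
  .emit_features(instances, stats, "bluetooth", "doryab", zero_fill = zf)
}

#' Conversation features
#'
#' Audio inference classes: 0 silence, 1 noise, 2 voice, 3 unknown. Minutes
#' per class are distinct sampled minutes carrying that class; conversations
#' are maximal voice runs with inter-row gaps of at most one minute.
#' Sensed fractions divide by total sensed minutes, expected fractions by the
#' segment's length in minutes.
#' @param assigned assigned conversation rows (inference, double_energy)
#' @param instances instance table
#' @export
conversation_features <- function(assigned, instances) {
  cls_names <- c("silence", "noise", "voice", "unknown")
  stats <- if (nrow(assigned)) assigned[, {
    minute_bin <- floor(timestamp / 60000)
    seg_minutes <- (seg_end_utc_ms[1] - seg_start_utc_ms[1]) / 60000
    out <- list()
    for (ci in 0:3) {
      out[[paste0("minutes", cls_names[ci + 1])]] <-
        as.numeric(data.table::uniqueN(minute_bin[inference == ci]))
    }
    sensed <- as.numeric(data.table::uniqueN(minute_bin))
    v <- .SD[inference == 2][order(timestamp)]
    if (nrow(v)) {
      brk <- c(TRUE, diff(v$timestamp) > 60000)
      g <- cumsum(brk)
      runs <- v[, .(start = min(timestamp), end = max(timestamp),
                    start_minute = local_minute[1]), by = .(g2 = g)]
      rd <- pmax((runs$end - runs$start) / 60000, 1 / 60)
      out$countconversation <- as.numeric(nrow(runs))
      out$sumconversationduration <- sum(rd)
      out$maxconversationduration <- max(rd)
      out$minconversationduration <- min(rd)
      out$avgconversationduration <- mean(rd)
      out$sdconversationduration <- .sd_or_na(rd)
      out$timefirstconversation <- runs$start_minute[1]
      out$timelastconversation <- runs$start_minute[nrow(runs)]
    } else {
      out$countconversation <- 0
      out[c("sumconversationduration", "maxconversationduration",
            "minconversationduration", "avgconversationduration",
            "sdconversationduration", "timefirstconversation",
            "timelastconversation")] <- NA_real_
      out$sumconversationduration <- 0
    }
    for (nm in c("noise", "voice")) {
      ci <- if (nm == "noise") 1L else 2L
      e <- double_energy[inference == ci]
      out[[paste0("sumenergy", nm)]] <- if (length(e)) sum(e) else 0
      out[[paste0("avgenergy", nm)]] <- if (length(e)) mean(e) else NA_real_
      out[[paste0("sdenergy", nm)]] <- .sd_or_na(e)
      out[[paste0("minenergy", nm)]] <- if (length(e)) min(e) else NA_real_
      out[[paste0("maxenergy", nm)]] <- if (length(e)) max(e) else NA_real_
    }
    for (ci in 0:3) {
      m <- out[[paste0("minutes", cls_names[ci + 1])]]
      out[[paste0(cls_names[ci + 1], "sensedfraction")]] <-
        if (sensed > 0) m / sensed else NA_real_
      out[[paste0(cls_names[ci + 1], "expectedfraction")]] <-
        if (seg_minutes > 0) m / seg_minutes else NA_real_
    }
    out
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "conversation", "rapids",
                 zero_fill = c(paste0("minutes", cls_names),
                               "countconversation", "sumconversationduration",
                               "sumenergynoise", "sumenergyvoice"))
}

#' Keyboard features
#'
#' Typing sessions are maximal keystroke runs with inter-key delays of at
#' most `session_gap_s` (default 5 s). Text-length change bins compare
#' `current_text` with `before_text` per keystroke.
#' @param assigned assigned keyboard rows
#' @param instances instance table
#' @param session_gap_s session-breaking inter-key gap, seconds
#' @export
keyboard_features <- function(assigned, instances, session_gap_s = 5) {
  stats <- if (nrow(assigned)) assigned[order(timestamp), {
    delays <- diff(timestamp)
    brk <- c(TRUE, delays > session_gap_s * 1000)
    g <- cumsum(brk)
    sess_len <- tapply(timestamp, g, function(t) (max(t) - min(t)) / 1000)
    within <- delays[!brk[-1]]
    delta <- nchar(as.character(current_text)) -
      nchar(as.character(before_text))
    list(sessioncount = as.numeric(max(g)),
         averagesessionlength = mean(sess_len),
         maxtextlength = as.numeric(max(nchar(as.character(current_text)))),
         totalkeyboardtouches = as.numeric(.N),
         averageinterkeydelay = if (length(within)) mean(within) else NA_real_,
         stdinterkeydelay = .sd_or_na(within),
         changeintextlengthlessthanminusone = as.numeric(sum(delta < -1)),
         changeintextlengthequaltominusone = as.numeric(sum(delta == -1)),
         changeintextlengthequaltoone = as.numeric(sum(delta == 1)),
         changeintextlengthmorethanone = as.numeric(sum(delta > 1)))
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "keyboard", "rapids",
                 zero_fill = c("sessioncount", "totalkeyboardtouches",
                               "maxtextlength",
                               paste0("changeintextlength",
                                      c("lessthanminusone", "equaltominusone",
                                        "equaltoone", "morethanone"))))
}

#' Accelerometer magnitude features
#'
#' max/min/avg/median/std of the Euclidean magnitude sqrt(x^2 + y^2 + z^2).
#' @param assigned assigned accelerometer rows (double_values_0..2)
#' @param instances instance table
#' @param sensor catalog sensor name
#' @export
accelerometer_features <- function(assigned, instances,
                                   sensor = "accelerometer") {
  stats <- if (nrow(assigned)) assigned[, {
    m <- sqrt(double_values_0^2 + double_values_1^2 + double_values_2^2)
    list(maxmagnitude = max(m), minmagnitude = min(m), avgmagnitude = mean(m),
         medianmagnitude = median(m), stdmagnitude = .sd_or_na(m))
  }, by = instance_id] else NULL
  .emit_features(instances, stats, sensor, "rapids")
}

#' Exertional-activity bout features from accelerometer magnitude
#'
#' A sampled minute is exertional when its mean magnitude is at or above
#' `threshold` (default 12 m/s^2, i.e. noticeably above rest gravity); bouts
#' are maximal runs of consecutive exertional minutes. Emits episode count
#' and duration sum/max/min/avg/std in minutes.
#' @param assigned assigned accelerometer rows
#' @param instances instance table
#' @param threshold exertion threshold on mean per-minute magnitude
#' @export
accelerometer_exertion_features <- function(assigned, instances,
                                            threshold = 12) {
  stats <- if (nrow(assigned)) assigned[, {
    m <- sqrt(double_values_0^2 + double_values_1^2 + double_values_2^2)
    minute <- floor(timestamp / 60000)
    per_min <- tapply(m, minute, mean)
    mins <- as.numeric(names(per_min))
    active <- per_min >= threshold
    runs <- rle(active[order(mins)])
    # break runs at non-consecutive minutes
    omins <- mins[order(mins)]
    grp <- cumsum(c(TRUE, diff(omins) > 1 |
                      active[order(mins)][-1] != head(active[order(mins)], -1)))
    lens <- tapply(omins, grp, length)
    act <- tapply(active[order(mins)], grp, function(x) x[1])
    d <- as.numeric(lens[act])
    if (!length(d)) {
      list(countepisodeexertionalactivityepisode = 0,
           sumdurationexertionalactivityepisode = 0,
           maxdurationexertionalactivityepisode = NA_real_,
           mindurationexertionalactivityepisode = NA_real_,
           avgdurationexertionalactivityepisode = NA_real_,
           stddurationexertionalactivityepisode = NA_real_)
    } else {
      list(countepisodeexertionalactivityepisode = as.numeric(length(d)),
           sumdurationexertionalactivityepisode = sum(d),
           maxdurationexertionalactivityepisode = max(d),
           mindurationexertionalactivityepisode = min(d),
           avgdurationexertionalactivityepisode = mean(d),
           stddurationexertionalactivityepisode = .sd_or_na(d))
    }
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "accelerometer", "panda",
                 zero_fill = c("countepisodeexertionalactivityepisode",
                               "sumdurationexertionalactivityepisode"))
}

#' Data-yield features
#'
#' `ratiovalidyieldedminutes`: fraction of the segment's minutes containing
#' at least one row from any configured sensor of the device class.
#' `ratiovalidyieldedhours`: fraction of the segment's hours whose own
#' yielded-minute ratio reaches `hour_threshold` (default 0.5). Both clipped
#' to [0, 1]. Minute and hour bins are anchored at the segment's UTC start.
#'
#' @param assigned union of assigned rows from all configured sensors
#'   (only `timestamp`, `instance_id` used)
#' @param instances instance table
#' @param hour_threshold per-hour validity threshold in (0, 1]
#' @param sensor catalog sensor name ("data_yield" or "fitbit_data_yield")
#' @export
data_yield_features <- function(assigned, instances, hour_threshold = 0.5,
                                sensor = "data_yield") {
  stopifnot(hour_threshold > 0, hour_threshold <= 1)
  inst <- as.data.table(instances)
  if (any(inst$end_wall <= inst$start_wall)) {
    .stopf("data yield: zero-length segment instance")
  }
  stats <- if (nrow(assigned)) assigned[, {
    seg_min <- (seg_end_utc_ms[1] - seg_start_utc_ms[1]) / 60000
    mb <- floor((timestamp - seg_start_utc_ms[1]) / 60000)
    mb <- unique(mb[mb >= 0 & mb < seg_min])
    hours_total <- seg_min / 60
    hb <- floor(mb / 60)
    per_hour <- tapply(mb, hb, length)
    hour_len <- pmin(60, seg_min - as.numeric(names(per_hour)) * 60)
    valid_hours <- sum(per_hour / hour_len >= hour_threshold)
    list(ratiovalidyieldedminutes =
           max(0, min(1, length(mb) / seg_min)),
         ratiovalidyieldedhours =
           max(0, min(1, valid_hours / hours_total)))
  }, by = instance_id] else NULL
  .emit_features(instances, stats, sensor, "rapids",
                 zero_fill = c("ratiovalidyieldedminutes",
                               "ratiovalidyieldedhours"))
}
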