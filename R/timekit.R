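# Time-zone localization and flexible time segments.
#
# Conventions, stated once:
#   * All intervals are half-open [start, end).
#   * Raw timestamps are UTC epoch milliseconds. Conversion is UTC -> local,
#     so nonexistent local times never arise from row localization.
#   * Local wall times are carried as POSIXct labeled UTC whose clock reads
#     the local wall time ("wall" columns). One column can then hold wall
#     times from different zones, and wall-clock arithmetic stays exact.
#   * Segment boundaries defined in wall time are mapped to UTC as the
#     earliest UTC instant whose local time reaches the boundary
#     (DST gap -> the transition instant; DST fold -> first occurrence).
#     Consequently both instants of a repeated autumn hour fall inside the
#     same local segment, and a wall window swallowed by a spring-forward
#     gap has an empty UTC span.

.ROLL_DST <- c("boundary", "pre")

.parse_duration_s <- function(x, allow_zero = FALSE) {
  # "90s", "30m", "6h", "2d", combinations "23h 59m 59s", "24h-1s", or a
  # bare number (minutes).
  x <- trimws(x)
  if (allow_zero && grepl("^0+[smhd]?$", x)) return(0)
  if (grepl("^[0-9]+(\\.[0-9]+)?$", x)) return(as.numeric(x) * 60)
  unit_s <- c(s = 1, m = 60, h = 3600, d = 86400)
  tokens <- gregexpr("([+-]?)\\s*([0-9]+(?:\\.[0-9]+)?)\\s*([smhd])",
                     tolower(x), perl = TRUE)
  m <- regmatches(tolower(x), tokens)[[1]]
  if (!length(m) || !nzchar(gsub("[-+0-9.smhd ]", "", tolower(x)))) {
    if (!length(m)) .stopf("cannot parse duration '%s'", x)
  }
  total <- 0
  for (tok in m) {
    sign <- if (startsWith(tok, "-")) -1 else 1
    num <- as.numeric(gsub("[^0-9.]", "", tok))
    unit <- substr(tok, nchar(tok), nchar(tok))
    total <- total + sign * num * unit_s[[unit]]
  }
  if (total <= 0) .stopf("duration '%s' must be positive", x)
  total
}

# tz active at a UTC epoch-ms instant under an ordered history
.tz_at <- function(ts_ms, tz_history) {
  idx <- findInterval(ts_ms, tz_history$start_utc_ms)
  if (any(idx == 0L)) {
    .warnf("%d timestamp(s) precede the first time-zone interval; using it",
           sum(idx == 0L))
    idx[idx == 0L] <- 1L
  }
  tz_history$tz[idx]
}

#' Localize UTC epoch-millisecond timestamps under a time-zone history
#'
#' Picks, per timestamp, the last history interval whose start is at or
#' before it, and converts using historical IANA rules (DST included).
#'
#' @param ts_utc_ms numeric vector, epoch milliseconds UTC
#' @param tz_history data.table (tz, start_utc_ms), sorted ascending
#' @return data.table with `tz` and `local_wall` (POSIXct labeled UTC whose
#'   clock reads local wall time)
#' @export
#' @examples
#' h <- data.table::data.table(tz = "America/New_York", start_utc_ms = 0)
#' localize(1583650740000, h)  # 2020-03-08 01:59 EST
localize <- function(ts_utc_ms, tz_history) {
  if (is.null(tz_history) || !nrow(tz_history)) .stopf("empty tz history")
  tzs <- .tz_at(ts_utc_ms, tz_history)
  wall <- .POSIXct(rep(NA_real_, length(ts_utc_ms)), tz = "UTC")
  for (z in unique(tzs)) {
    sel <- tzs == z
    loc <- .POSIXct(ts_utc_ms[sel] / 1000, tz = z)
    wall[sel] <- lubridate::force_tz(loc, "UTC")
  }
  data.table(tz = tzs, local_wall = wall)
}

# wall (UTC-labeled POSIXct) + zone name -> UTC epoch ms, gap/fold policy above
.wall_to_utc_ms <- function(wall, tz) {
  out <- numeric(length(wall))
  for (z in unique(tz)) {
    sel <- tz == z
    real <- lubridate::force_tz(wall[sel], z, roll_dst = .ROLL_DST)
    out[sel] <- as.numeric(real) * 1000
  }
  out
}

#' Localize a raw stream in place
#'
#' Adds `tz`, `local_wall`, `local_date`, and `local_minute` (minutes since
#' local midnight) columns.
#' @param stream a `raw_stream`
#' @param tz_history participant tz history
#' @return the stream (invisibly modified copy)
#' @export
localize_stream <- function(stream, tz_history) {
  out <- copy(stream)
  if (!nrow(out)) {
    out[, `:=`(tz = character(0),
               local_wall = .POSIXct(numeric(0), tz = "UTC"),
               local_date = as.Date(character(0)),
               local_minute = numeric(0))]
    return(out[])
  }
  loc <- localize(out$timestamp, tz_history)
  out[, `:=`(tz = loc$tz, local_wall = loc$local_wall)]
  out[, local_date := as.Date(lubridate::floor_date(local_wall, "day"))]
  out[, local_minute := .minutes_since_midnight(local_wall)]
  out[]
}

# ---- segment specs ----

#' Read a time-segment definition file
#'
#' CSV columns: `label, kind, length, start_time, repeat_type, repeat_value,
#' shift, shift_direction, event_file`. `kind` is one of `frequency`,
#' `periodic`, `event`. Lengths/shifts use duration syntax like `30m`, `6h`,
#' `24h-1s`, or bare minutes. `repeat_type` is `every_day`, `day_of_week`
#' (value 1=Monday..7=Sunday or a weekday name), `day_of_month`,
#' `day_of_quarter`, or `day_of_year`.
#' @param path CSV path
#' @return list of segment_spec objects
#' @export
read_segment_specs <- function(path) {
  if (!file.exists(path)) .stopf("segment file '%s' does not exist", path)
  df <- fread(path, colClasses = "character", fill = TRUE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i])
    segment_spec(label = r$label, kind = r$kind, length = r$length,
                 start_time = r$start_time %||% "00:00:00",
                 repeat_type = r$repeat_type %||% "every_day",
                 repeat_value = suppressWarnings(as.integer(r$repeat_value)),
                 shift = r$shift %||% "0s",
                 shift_direction = r$shift_direction %||% "after",
                 event_file = r$event_file %||% NA_character_)
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a) || !nzchar(a)) b else a

#' Construct a segment specification
#' @param label segment label (unique per study)
#' @param kind "frequency", "periodic", or "event"
#' @param length window duration (duration syntax or minutes)
#' @param start_time local clock time "HH:MM[:SS]" (periodic only)
#' @param repeat_type,repeat_value periodic repeat rule
#' @param shift,shift_direction event anchoring ("before"/"after")
#' @param event_file per-participant event CSV (event kind only)
#' @return a `segment_spec`
#' @export
segment_spec <- function(label, kind, length, start_time = "00:00:00",
                         repeat_type = "every_day", repeat_value = NA_integer_,
                         shift = "0s", shift_direction = "after",
                         event_file = NA_character_) {
  kind <- match.arg(kind, c("frequency", "periodic", "event"))
  len_s <- .parse_duration_s(length)
  if (kind == "frequency") {
    len_min <- len_s / 60
    if (len_min != round(len_min) || 1440 %% len_min != 0) {
      .stopf("frequency segment '%s': length %s does not divide 1440 minutes",
             label, length)
    }
  }
  if (kind == "event" && !shift_direction %in% c("before", "after")) {
    .stopf("event segment '%s': shift_direction must be before/after", label)
  }
  ok_repeat <- c("every_day", "day_of_week", "day_of_month", "day_of_quarter",
                 "day_of_year")
  if (kind == "periodic" && !repeat_type %in% ok_repeat) {
    .stopf("periodic segment '%s': unknown repeat_type '%s'", label, repeat_type)
  }
  structure(list(label = label, kind = kind, length_s = len_s,
                 start_time = start_time, repeat_type = repeat_type,
                 repeat_value = repeat_value,
                 shift_s = .parse_duration_s(shift, allow_zero = TRUE),
                 shift_direction = shift_direction, event_file = event_file),
            class = "segment_spec")
}

.empty_instances <- function() {
  data.table(pid = character(0), label = character(0),
             instance_id = character(0),
             start_wall = .POSIXct(numeric(0), tz = "UTC"),
             end_wall = .POSIXct(numeric(0), tz = "UTC"),
             tz = character(0), start_utc_ms = numeric(0),
             end_utc_ms = numeric(0), local_date = as.Date(character(0)))
}

.finish_instances <- function(inst) {
  if (!nrow(inst)) return(.empty_instances())
  inst[, start_utc_ms := .wall_to_utc_ms(start_wall, tz)]
  inst[, end_utc_ms := .wall_to_utc_ms(end_wall, tz)]
  setorder(inst, start_utc_ms, label, instance_id)
  inst[]
}

# dates in enrollment with the tz active at each date's UTC midnight
.dates_with_tz <- function(local_dates, tz_history) {
  ms <- as.numeric(as.POSIXct(paste(local_dates, "00:00:00"), tz = "UTC")) * 1000
  data.table(local_date = local_dates, tz = .tz_at(ms, tz_history))
}

#' Expand a frequency segment spec over a date range
#'
#' Contiguous wall-clock windows `[00:00 + k*length, 00:00 + (k+1)*length)`
#' tile every nominal day; exactly `1440/length` instances per day. On a
#' spring-forward day a window swallowed by the DST gap has an empty UTC span
#' (it can never contain data); on a fall-back day the window containing the
#' repeated hour covers both UTC instants.
#'
#' @param spec frequency `segment_spec`
#' @param local_dates Date vector of study days
#' @param pid participant id
#' @param tz_history tz history table
#' @return instance table (pid, label, instance_id, wall + UTC boundaries)
#' @export
expand_frequency <- function(spec, local_dates, pid, tz_history) {
  stopifnot(spec$kind == "frequency")
  if (!length(local_dates)) return(.empty_instances())
  dtz <- .dates_with_tz(local_dates, tz_history)
  k <- 0:(86400 / spec$length_s - 1)
  inst <- dtz[, {
    day0 <- as.POSIXct(paste(local_date, "00:00:00"), tz = "UTC")
    .(instance_id = sprintf("%s#%s#%04d", spec$label, local_date, k),
      start_wall = day0 + k * spec$length_s,
      end_wall = day0 + (k + 1) * spec$length_s)
  }, by = .(local_date, tz)]
  inst[, `:=`(pid = pid, label = spec$label)]
  .finish_instances(inst)
}

.matches_rule <- function(dates, type, value) {
  switch(type,
    every_day = rep(TRUE, length(dates)),
    day_of_week = lubridate::wday(dates, week_start = 1) == value,
    day_of_month = lubridate::mday(dates) == value,
    day_of_quarter = lubridate::qday(dates) == value,
    day_of_year = lubridate::yday(dates) == value,
    .stopf("unknown repeat_type '%s'", type))
}

#' Expand a periodic segment spec over a date range
#'
#' One instance per matching day, starting at `start_time` local wall clock,
#' lasting `length`; instances may span midnights (and month ends).
#' @inheritParams expand_frequency
#' @export
expand_periodic <- function(spec, local_dates, pid, tz_history) {
  stopifnot(spec$kind == "periodic")
  sel <- .matches_rule(local_dates, spec$repeat_type, spec$repeat_value)
  days <- local_dates[sel]
  if (!length(days)) return(.empty_instances())
  dtz <- .dates_with_tz(days, tz_history)
  st <- if (grepl("^\\d{2}:\\d{2}$", spec$start_time)) {
    paste0(spec$start_time, ":00")
  } else spec$start_time
  inst <- dtz[, {
    s <- as.POSIXct(paste(local_date, st), tz = "UTC")
    .(instance_id = sprintf("%s#%s", spec$label, local_date),
      start_wall = s, end_wall = s + spec$length_s)
  }, by = .(local_date, tz)]
  inst[, `:=`(pid = pid, label = spec$label)]
  .finish_instances(inst)
}

#' Expand an event segment spec around per-participant events
#'
#' Each event timestamp is localized under the participant's tz history; the
#' window is anchored at the local event time, shifted by `shift` in
#' `shift_direction`. With direction "before" the window ENDS `shift` before
#' the event (`shift = 0` gives `[t - length, t)`); with "after" it STARTS
#' `shift` after the event.
#'
#' @param spec event `segment_spec`
#' @param events data.table (pid, event_timestamp_utc_ms)
#' @param pid participant id (events for other pids are skipped with warning)
#' @param tz_history tz history table
#' @export
expand_event <- function(spec, events, pid, tz_history) {
  stopifnot(spec$kind == "event")
  if (is.null(events) || !nrow(events)) return(.empty_instances())
  sel <- events$pid == pid   # evaluate outside [] to avoid column capture
  if (any(!sel)) {
    .warnf("skipping %d event(s) for pid(s) not matching '%s'", sum(!sel), pid)
  }
  ev <- events[which(sel)]
  if (!nrow(ev)) return(.empty_instances())
  loc <- localize(ev$event_timestamp_utc_ms, tz_history)
  anchor <- loc$local_wall
  if (spec$shift_direction == "after") {
    start_wall <- anchor + spec$shift_s
  } else {
    start_wall <- anchor - spec$shift_s - spec$length_s
  }
  inst <- data.table(
    local_date = as.Date(lubridate::floor_date(anchor, "day")),
    tz = loc$tz,
    instance_id = sprintf("%s#%d#%.0f", spec$label, seq_len(nrow(ev)),
                          ev$event_timestamp_utc_ms),
    start_wall = start_wall,
    end_wall = start_wall + spec$length_s,
    pid = pid, label = spec$label)
  .finish_instances(inst)
}

#' Expand any segment spec for one participant
#' @param spec a `segment_spec`
#' @param participant a `participant`
#' @param events optional event table for event specs
#' @return instance table
#' @export
expand_segments <- function(spec, participant, events = NULL) {
  days <- seq(participant$enrollment[["start"]], participant$enrollment[["end"]],
              by = "day")
  switch(spec$kind,
    frequency = expand_frequency(spec, days, participant$pid,
                                 participant$tz_history),
    periodic = expand_periodic(spec, days, participant$pid,
                               participant$tz_history),
    event = expand_event(spec, events, participant$pid, participant$tz_history))
}

#' Assign localized rows to segment instances
#'
#' A row belongs to every instance whose `[start, end)` UTC interval contains
#' its timestamp; rows inside overlapping instances appear once per instance.
#' Assignment is stable under row order.
#'
#' @param rows localized stream (needs `timestamp`)
#' @param instances instance table from the expand_* family
#' @return data.table: one row per (row, matching instance), with instance
#'   columns `label`, `instance_id`, `seg_start_utc_ms`, `seg_end_utc_ms`,
#'   `seg_start_wall`, `seg_end_wall` appended
#' @export
assign_segments <- function(rows, instances) {
  if (!nrow(rows) || !nrow(instances)) {
    out <- copy(rows[0])
    out[, `:=`(label = character(0), instance_id = character(0),
               seg_start_utc_ms = numeric(0), seg_end_utc_ms = numeric(0),
               seg_start_wall = .POSIXct(numeric(0), "UTC"),
               seg_end_wall = .POSIXct(numeric(0), "UTC"))]
    return(out[])
  }
  r <- copy(as.data.table(rows))
  r[, `:=`(.row_id = .I, .ts0 = timestamp, .ts1 = timestamp)]
  i <- as.data.table(instances)[start_utc_ms < end_utc_ms]
  ans <- r[i, on = .(.ts0 >= start_utc_ms, .ts1 < end_utc_ms), nomatch = NULL,
           allow.cartesian = TRUE,
           .(row_id = x..row_id, label = i.label, instance_id = i.instance_id,
             seg_start_utc_ms = i.start_utc_ms, seg_end_utc_ms = i.end_utc_ms,
             seg_start_wall = i.start_wall, seg_end_wall = i.end_wall)]
  r[, c(".ts0", ".ts1") := NULL]
  out <- r[ans, on = .(.row_id = row_id)]
  out[, .row_id := NULL]
  setorder(out, timestamp, instance_id)
  out[]
}
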