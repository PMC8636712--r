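# Interval episodes reconstructed from event logs, and their splitting at
# segment boundaries. Episodes live in UTC epoch milliseconds; splitting
# intersects them with segment instances' UTC intervals, so wall-clock and
# DST subtleties are already resolved upstream.

.empty_episodes <- function() {
  data.table(kind = character(0), start_utc_ms = numeric(0),
             end_utc_ms = numeric(0), truncated = logical(0))
}

#' Build screen-session episodes from a screen event stream
#'
#' Android: a session runs from each unlock (status 3) to the next off
#' (status 0); lock (2) events inside a session are ignored. iOS: unlock (3)
#' to the next locked (2). Orphan lock/off events are ignored. A trailing
#' unlock with no terminator is closed at the last observed screen row and
#' flagged `truncated`.
#'
#' @param stream screen `raw_stream` (columns timestamp, screen_status)
#' @param platform "android" or "ios"
#' @return episode table (kind, start_utc_ms, end_utc_ms, truncated)
#' @export
screen_episodes <- function(stream, platform = c("android", "ios")) {
  platform <- match.arg(platform)
  if (!nrow(stream)) return(.empty_episodes())
  dom <- .screen_domain[[platform]]
  bad <- !(stream$screen_status %in% dom)
  if (any(bad)) {
    .warnf("screen: dropping %d row(s) with out-of-domain status", sum(bad))
  }
  ev <- stream[!bad][order(timestamp)]
  terminator <- if (platform == "android") 0L else 2L
  starts <- numeric(0); ends <- numeric(0); trunc <- logical(0)
  open_at <- NA_real_
  for (i in seq_len(nrow(ev))) {
    st <- ev$screen_status[i]
    if (st == 3L && is.na(open_at)) {
      open_at <- ev$timestamp[i]
    } else if (st == terminator && !is.na(open_at)) {
      if (ev$timestamp[i] > open_at) {
        starts <- c(starts, open_at); ends <- c(ends, ev$timestamp[i])
        trunc <- c(trunc, FALSE)
      }
      open_at <- NA_real_
    }
  }
  if (!is.na(open_at) && tail(ev$timestamp, 1) > open_at) {
    starts <- c(starts, open_at); ends <- c(ends, tail(ev$timestamp, 1))
    trunc <- c(trunc, TRUE)
  }
  data.table(kind = rep("screen_unlock", length(starts)),
             start_utc_ms = starts, end_utc_ms = ends, truncated = trunc)
}

#' Build battery charge/discharge episodes from battery level samples
#'
#' Maximal runs of consecutive rows with non-increasing level form discharge
#' episodes (a constant level therefore discharges with drop 0); strictly
#' increasing runs form charge episodes. Runs with a single row are dropped.
#' Attributes: start/end level, level drop (discharge) or gain (charge), and
#' rate in percent per hour.
#'
#' @param stream battery `raw_stream` (timestamp, battery_level in 0..100)
#' @return episode table with level/rate attribute columns
#' @export
battery_episodes <- function(stream) {
  empty <- data.table(kind = character(0), start_utc_ms = numeric(0),
                      end_utc_ms = numeric(0), level_start = numeric(0),
                      level_end = numeric(0), delta = numeric(0),
                      rate_per_h = numeric(0), truncated = logical(0))
  if (!nrow(stream)) return(empty)
  bad <- stream$battery_level < 0 | stream$battery_level > 100 |
    is.na(stream$battery_level)
  if (any(bad)) .warnf("battery: rejecting %d row(s) with level outside [0,100]",
                       sum(bad))
  b <- stream[!bad][order(timestamp)]
  if (nrow(b) < 2L) return(empty)
  inc <- diff(b$battery_level) > 0          # TRUE -> charging step
  runs <- rle(inc)
  idx_end <- cumsum(runs$lengths)
  idx_start <- c(1L, head(idx_end, -1) + 1L)
  out <- lapply(seq_along(runs$values), function(k) {
    i0 <- idx_start[k]; i1 <- idx_end[k] + 1L   # step k spans rows k..k+1
    dur_h <- (b$timestamp[i1] - b$timestamp[i0]) / 3.6e6
    delta <- b$battery_level[i1] - b$battery_level[i0]
    data.table(kind = if (runs$values[k]) "battery_charge" else
                 "battery_discharge",
               start_utc_ms = b$timestamp[i0], end_utc_ms = b$timestamp[i1],
               level_start = b$battery_level[i0],
               level_end = b$battery_level[i1],
               delta = abs(delta),
               rate_per_h = if (dur_h > 0) abs(delta) / dur_h else NA_real_,
               truncated = FALSE)
  })
  rbindlist(out)
}

#' Build activity bouts from activity-recognition rows
#'
#' Consecutive rows with the same activity class form a bout; a gap above
#' `max_gap_s` (default 300 s) breaks the bout. Classes are mapped onto
#' \{stationary, mobile, vehicle\}.
#' @param stream activity_recognition `raw_stream`
#' @param max_gap_s gap cap in seconds
#' @return episode table with `activity_class` attribute
#' @export
activity_episodes <- function(stream, max_gap_s = 300) {
  map <- c(still = "stationary", tilting = "stationary",
           on_foot = "mobile", walking = "mobile", running = "mobile",
           on_bicycle = "mobile", in_vehicle = "vehicle")
  empty <- data.table(kind = character(0), start_utc_ms = numeric(0),
                      end_utc_ms = numeric(0), activity_class = character(0),
                      truncated = logical(0))
  if (!nrow(stream)) return(empty)
  a <- stream[order(timestamp)]
  cls <- map[as.character(a$activity_type)]
  cls[is.na(cls)] <- "stationary"
  brk <- c(TRUE, cls[-1] != head(cls, -1) |
             diff(a$timestamp) > max_gap_s * 1000)
  grp <- cumsum(brk)
  out <- a[, .(start_utc_ms = min(timestamp), end_utc_ms = max(timestamp)),
           by = .(g = grp, c = cls)]
  out <- out[end_utc_ms > start_utc_ms]
  data.table(kind = "activity", start_utc_ms = out$start_utc_ms,
             end_utc_ms = out$end_utc_ms, activity_class = out$c,
             truncated = FALSE)
}

#' Build sleep-stage episodes from Fitbit intraday rows
#'
#' Per-minute stage rows become maximal constant-stage episodes; each row is
#' taken to cover one minute. Classic-log levels asleep/restless/awake map to
#' asleep/light/awake.
#' @param stream fitbit_sleep_intraday `raw_stream` (timestamp, level, type)
#' @return episode table with `stage` and `sleep_type` attributes
#' @export
sleep_episodes <- function(stream) {
  empty <- data.table(kind = character(0), start_utc_ms = numeric(0),
                      end_utc_ms = numeric(0), stage = character(0),
                      sleep_type = character(0), truncated = logical(0))
  if (!nrow(stream)) return(empty)
  map <- c(awake = "awake", wake = "awake", light = "light", deep = "deep",
           rem = "rem", asleep = "asleep", restless = "light")
  s <- stream[order(timestamp)]
  stage <- unname(map[as.character(s$level)])
  brk <- c(TRUE, stage[-1] != head(stage, -1) |
             s$type[-1] != head(s$type, -1) |
             diff(s$timestamp) > 60000)
  grp <- cumsum(brk)
  out <- s[, .(start_utc_ms = min(timestamp),
               end_utc_ms = max(timestamp) + 60000,
               stage = stage[.I][1], sleep_type = type[1]),
           by = .(g = grp)]
  data.table(kind = "sleep", start_utc_ms = out$start_utc_ms,
             end_utc_ms = out$end_utc_ms, stage = out$stage,
             sleep_type = out$sleep_type, truncated = FALSE)
}

#' Split episodes at segment-instance boundaries
#'
#' Intersects every episode with every overlapping instance of the same
#' participant. Fragment durations per episode sum exactly (to the
#' millisecond) to the portion of the episode covered by instances; all
#' attribute columns are inherited.
#'
#' @param episodes episode table (start_utc_ms, end_utc_ms, attributes)
#' @param instances segment instance table
#' @return fragment table: episode attributes + instance identity +
#'   `frag_start_utc_ms`, `frag_end_utc_ms`, `frag_minutes`
#' @export
split_on_boundaries <- function(episodes, instances) {
  attrs <- setdiff(names(episodes), c("start_utc_ms", "end_utc_ms"))
  if (!nrow(episodes) || !nrow(instances)) {
    out <- copy(episodes[0])
    out[, `:=`(label = character(0), instance_id = character(0),
               seg_start_utc_ms = numeric(0), seg_end_utc_ms = numeric(0),
               seg_start_wall = .POSIXct(numeric(0), "UTC"),
               frag_start_utc_ms = numeric(0), frag_end_utc_ms = numeric(0),
               frag_minutes = numeric(0))]
    return(out[])
  }
  e <- copy(as.data.table(episodes))
  e[, .eid := .I]
  i <- as.data.table(instances)[start_utc_ms < end_utc_ms]
  ov <- e[i, on = .(start_utc_ms < end_utc_ms, end_utc_ms > start_utc_ms),
          nomatch = NULL, allow.cartesian = TRUE,
          .(eid = x..eid, label = i.label, instance_id = i.instance_id,
            seg_start_utc_ms = i.start_utc_ms, seg_end_utc_ms = i.end_utc_ms,
            seg_start_wall = i.start_wall)]
  if (!nrow(ov)) return(split_on_boundaries(episodes[0], instances))
  out <- e[ov, on = .(.eid = eid)]
  out[, frag_start_utc_ms := pmax(start_utc_ms, seg_start_utc_ms)]
  out[, frag_end_utc_ms := pmin(end_utc_ms, seg_end_utc_ms)]
  out <- out[frag_end_utc_ms > frag_start_utc_ms]
  out[, frag_minutes := (frag_end_utc_ms - frag_start_utc_ms) / 60000]
  out[, c(".eid", "start_utc_ms", "end_utc_ms") := NULL]
  setorder(out, frag_start_utc_ms, instance_id)
  out[]
}

#' Write or read the inspectable intermediate episode file
#' @param episodes episode table
#' @param path CSV destination
#' @export
write_episodes <- function(episodes, path) {
  fwrite(episodes, path)
  invisible(path)
}
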