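# Participant registry, time-zone history, and raw-stream loading with
# multi-device merging. On-disk dialect: comma-delimited UTF-8 CSV with a
# header row, one raw file per (device, sensor); timestamps are integer epoch
# milliseconds in UTC throughout (AWARE convention) and local-time math is
# deferred to the localization layer.

.PLATFORMS <- c(phone = "android|ios", fitbit = "fitbit", empatica = "empatica")

#' Read the participant registry
#'
#' The registry is a CSV with columns `pid`, `phone_ids`, `fitbit_ids`,
#' `empatica_ids` (each a semicolon-joined list, possibly empty), `platform`
#' (phone platform: `android` or `ios`), `start_date`, `end_date`
#' (`YYYY-MM-DD`, enrollment range in local time). Device lists may be empty;
#' several ids of one class describe device switching.
#'
#' @param path registry CSV
#' @param tz_path optional time-zone history CSV with columns
#'   `pid, tz, start_utc_ms`; participants without an entry default to UTC
#'   from epoch 0.
#' @return list of `participant` objects (pid, devices, enrollment, tz_history)
#' @export
read_participant_registry <- function(path, tz_path = NULL) {
  if (!file.exists(path)) .stopf("registry file '%s' does not exist", path)
  reg <- fread(path, colClasses = "character")
  need <- c("pid", "phone_ids", "fitbit_ids", "empatica_ids", "platform",
            "start_date", "end_date")
  missing <- setdiff(need, names(reg))
  if (length(missing)) {
    .stopf("registry missing column(s): %s", paste(missing, collapse = ", "))
  }
  dup <- reg$pid[duplicated(reg$pid)]
  if (length(dup)) .stopf("duplicate pid '%s' in registry", dup[1L])
  tzh <- if (!is.null(tz_path)) read_tz_history(tz_path) else NULL

  lapply(seq_len(nrow(reg)), function(i) {
    row <- reg[i]
    if (!row$platform %in% c("android", "ios")) {
      .stopf("participant '%s': unknown platform '%s'", row$pid, row$platform)
    }
    split_ids <- function(x) {
      ids <- strsplit(x, ";", fixed = TRUE)[[1]]
      ids[nzchar(ids)]
    }
    devices <- rbindlist(list(
      data.table(device_id = split_ids(row$phone_ids), device_class = "phone",
                 platform = row$platform),
      data.table(device_id = split_ids(row$fitbit_ids), device_class = "fitbit",
                 platform = "fitbit"),
      data.table(device_id = split_ids(row$empatica_ids),
                 device_class = "empatica", platform = "empatica")
    ))
    tz_history <- if (!is.null(tzh) && row$pid %in% tzh$pid) {
      tzh[tzh$pid == row$pid, c("tz", "start_utc_ms")]
    } else {
      data.table(tz = "UTC", start_utc_ms = 0)
    }
    p <- list(pid = row$pid, devices = devices,
              enrollment = c(start = as.Date(row$start_date),
                             end = as.Date(row$end_date)),
              tz_history = tz_history)
    class(p) <- "participant"
    p
  })
}

#' Read a time-zone history file
#'
#' CSV columns: `pid`, `tz` (IANA zone name), `start_utc_ms` (epoch ms when
#' the participant entered that zone). Per participant the entries must be
#' strictly ascending in `start_utc_ms`.
#' @param path CSV path
#' @return data.table (pid, tz, start_utc_ms) sorted within pid
#' @export
read_tz_history <- function(path) {
  if (!file.exists(path)) .stopf("tz history file '%s' does not exist", path)
  tzh <- fread(path)
  need <- c("pid", "tz", "start_utc_ms")
  if (length(setdiff(need, names(tzh)))) {
    .stopf("tz history must have columns %s", paste(need, collapse = ", "))
  }
  known <- c("UTC", "GMT", OlsonNames())
  for (i in seq_len(nrow(tzh))) {
    if (!tzh$tz[i] %in% known) {
      .stopf("tz history line %d: unknown time zone '%s'", i + 1L, tzh$tz[i])
    }
    if (is.na(tzh$start_utc_ms[i])) {
      .stopf("tz history line %d: malformed start_utc_ms", i + 1L)
    }
  }
  setorder(tzh, pid, start_utc_ms)
  bad <- tzh[, .(ok = !anyDuplicated(start_utc_ms)), by = pid][!(ok)]
  if (nrow(bad)) .stopf("tz history for '%s' not strictly ascending", bad$pid[1])
  tzh
}

#' @export
print.participant <- function(x, ...) {
  cat(sprintf("<participant %s: %d device(s), %s to %s, %d tz interval(s)>\n",
              x$pid, nrow(x$devices), x$enrollment["start"],
              x$enrollment["end"], nrow(x$tz_history)))
  invisible(x)
}

#' Load and merge one sensor's raw stream for a participant
#'
#' Concatenates rows from every file (one file per device), validates against
#' the sensor schema, sorts by timestamp, and drops rows that are exact
#' duplicates on ALL columns. Rows equal in timestamp but differing in any
#' payload column are both kept: two devices can legitimately log at the same
#' instant. Each retained row keeps its originating `device_id` (taken from a
#' `device_id` column, or injected from `device_ids[i]` if the file lacks one).
#'
#' @param participant a `participant` (or NULL when paths carry device ids)
#' @param sensor sensor name in [supported_sensors()]
#' @param paths character vector of CSV files
#' @param device_ids optional device id per path, used when files have no
#'   `device_id` column
#' @return a `raw_stream`: data.table sorted by timestamp, with attributes
#'   `sensor` and `pid`
#' @export
load_stream <- function(participant = NULL, sensor, paths,
                        device_ids = NULL) {
  pieces <- lapply(seq_along(paths), function(i) {
    f <- paths[[i]]
    if (!file.exists(f)) .stopf("stream file '%s' does not exist", f)
    dt <- fread(f)
    if (!nrow(dt)) return(NULL)
    dt <- .validate_stream(dt, sensor, f)
    if (!"device_id" %in% names(dt)) {
      # file layout is <data_root>/<device_id>/<sensor>.csv
      dt[, device_id := if (!is.null(device_ids)) device_ids[[i]] else
        basename(dirname(f))]
    }
    if (is.unsorted(dt$timestamp)) {
      .warnf("stream file '%s': non-monotone timestamps, sorting", f)
    }
    dt
  })
  merged <- rbindlist(pieces, use.names = TRUE, fill = TRUE)
  if (is.null(merged) || !nrow(merged)) {
    merged <- data.table(timestamp = numeric(0), device_id = character(0))
  }
  merged <- unique(merged)
  setorder(merged, timestamp, device_id)
  setattr(merged, "sensor", sensor)
  setattr(merged, "pid", if (!is.null(participant)) participant$pid else NA_character_)
  setattr(merged, "class", c("raw_stream", class(merged)))
  merged[]
}
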