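# Shared fixture builders. Everything is generated in code; the only state
# kept across tests is a memoized small synthetic study directory.

library(data.table)

UTC_TZH <- data.table(tz = "UTC", start_utc_ms = 0)
NY_TZH <- data.table(tz = "America/New_York", start_utc_ms = 0)

utc_ms <- function(s) as.numeric(as.POSIXct(s, tz = "UTC")) * 1000

# daily [00:00, 24:00) instances for given dates
daily_instances <- function(dates, pid = "p01", tzh = UTC_TZH) {
  expand_periodic(segment_spec("daily", "periodic", "24h"), as.Date(dates),
                  pid, tzh)
}

# localize + assign a raw table against instances in one go
assign_rows <- function(rows, instances, tzh = UTC_TZH) {
  assign_segments(localize_stream(as.data.table(rows), tzh), instances)
}

# one daily instance covering the date of the first row
quick_assign <- function(rows, tzh = UTC_TZH, pid = "p01") {
  st <- localize_stream(as.data.table(rows), tzh)
  inst <- daily_instances(unique(st$local_date), pid, tzh)
  list(assigned = assign_segments(st, inst), instances = inst)
}

feature_value <- function(fr, name, i = 1L) fr[[name]][i]

# memoized small synthetic study (3 participants, 3 days)
small_study_dir <- local({
  cache <- NULL
  function() {
    if (!is.null(cache) && dir.exists(cache)) return(cache)
    d <- file.path(tempdir(), "mobsense-small-study")
    if (!dir.exists(d)) {
      generate_study(synth_profile(seed = 7, days = 3), d)
    }
    cache <<- d
    d
  }
})

write_stream_csv <- function(dt, dir, device, sensor) {
  dd <- file.path(dir, device)
  dir.create(dd, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(dd, paste0(sensor, ".csv"))
  fwrite(dt, f)
  f
}
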