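# Stream schema registry. The published pipeline treats container formats as
# pluggable; this dialect is AWARE-style CSV with epoch-millisecond UTC
# timestamps. Every supported sensor has exactly one schema; categorical
# columns carry value domains so malformed codes are rejected at load time.

.screen_domain <- list(android = c(0L, 1L, 2L, 3L), ios = c(2L, 3L))

.schema_registry <- function() {
  s <- function(required, domains = list()) {
    list(required = c("timestamp", required), domains = domains)
  }
  list(
    calls = s(c("call_type", "call_duration", "trace"),
              list(call_type = c("incoming", "outgoing", "missed"))),
    sms = s(c("message_type", "trace"),
            list(message_type = c("sent", "received"))),
    screen = s("screen_status"),   # platform-dependent domain, checked later
    battery = s("battery_level"),
    light = s("double_light_lux"),
    accelerometer = s(c("double_values_0", "double_values_1", "double_values_2")),
    activity_recognition = s("activity_type"),
    applications_foreground = s(c("package_name", "application_name")),
    bluetooth = s("bt_address"),
    wifi_connected = s("mac_address"),
    wifi_visible = s("bssid"),
    conversation = s(c("double_energy", "inference"),
                     list(inference = 0:3)),  # 0 silence,1 noise,2 voice,3 unknown
    keyboard = s(c("package_name", "before_text", "current_text")),
    locations = s(c("double_latitude", "double_longitude", "accuracy")),
    fitbit_heartrate_intraday = s("heartrate"),
    fitbit_heartrate_summary = s(c("local_date", "heartrate_daily_restinghr",
                                   paste0("heartrate_", c("outofrange", "fatburn",
                                                          "cardio", "peak"),
                                          "_minutes"),
                                   paste0("heartrate_", c("outofrange", "fatburn",
                                                          "cardio", "peak"),
                                          "_calories"))),
    fitbit_steps_intraday = s("steps"),
    fitbit_steps_summary = s(c("local_date", "steps")),
    fitbit_sleep_intraday = s(c("level", "type"),
                              list(level = c("awake", "light", "deep", "rem",
                                             "asleep", "restless", "wake"),
                                   type = c("main", "nap"))),
    fitbit_sleep_summary = s(c("local_date", "type", "duration_ms",
                               "minutes_asleep", "minutes_awake", "efficiency"),
                             list(type = c("main", "nap"))),
    fitbit_calories_intraday = s(c("calories", "level"),
                                 list(level = c("sedentary", "lightlyactive",
                                                "fairlyactive", "veryactive"))),
    empatica_accelerometer = s(c("double_values_0", "double_values_1",
                                 "double_values_2")),
    empatica_heartrate = s("heartrate"),
    empatica_temperature = s("temperature"),
    empatica_electrodermal_activity = s("electrodermal_activity"),
    empatica_blood_volume_pulse = s("blood_volume_pulse"),
    empatica_inter_beat_interval = s("inter_beat_interval")
  )
}

#' Schema for one supported sensor
#' @param sensor sensor name
#' @return list with `required` column names and categorical `domains`
#' @export
stream_schema <- function(sensor) {
  reg <- .schema_registry()
  if (!sensor %in% names(reg)) .stopf("unsupported sensor '%s'", sensor)
  reg[[sensor]]
}

#' Names of all supported raw stream sensors
#' @return character vector
#' @export
supported_sensors <- function() names(.schema_registry())

# Validate a raw table against a sensor schema; returns the table (possibly
# with rows dropped) or stops on structural problems.
.validate_stream <- function(dt, sensor, file = "<memory>") {
  sch <- stream_schema(sensor)
  missing <- setdiff(sch$required, names(dt))
  if (length(missing)) {
    .stopf("stream '%s' (%s): missing required column(s) %s",
           sensor, file, paste(missing, collapse = ", "))
  }
  if (nrow(dt)) {
    if (!is.numeric(dt$timestamp) || anyNA(dt$timestamp)) {
      .stopf("stream '%s' (%s): non-numeric or missing timestamps", sensor, file)
    }
    for (col in names(sch$domains)) {
      bad <- !(dt[[col]] %in% sch$domains[[col]])
      if (any(bad)) {
        .warnf("stream '%s' (%s): dropping %d row(s) with out-of-domain '%s'",
               sensor, file, sum(bad), col)
        dt <- dt[!bad]
      }
    }
  }
  dt
}
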