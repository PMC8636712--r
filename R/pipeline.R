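# Pipeline orchestration: plain-text configuration, a per-(participant,
# sensor, provider) DAG, and incremental execution driven by content hashes.
# A stage re-executes iff any input file's hash or its parameter fingerprint
# differs from the recorded manifest; downstream stages of a re-run stage
# re-run. Outputs are plain CSV files inspectable at any time.

# raw stream backing each catalog sensor (NULL = derived/special)
.PROVIDER_STREAM <- list(
  calls_incoming = "calls", calls_outgoing = "calls", calls_missed = "calls",
  sms = "sms", screen = "screen", light = "light", battery = "battery",
  data_yield = NULL, activity_recognition = "activity_recognition",
  applications_foreground = "applications_foreground",
  wifi_connected = "wifi_connected", wifi_visible = "wifi_visible",
  bluetooth = "bluetooth", conversation = "conversation",
  keyboard = "keyboard", accelerometer = "accelerometer",
  locations = "locations",
  fitbit_data_yield = NULL,
  fitbit_heartrate_intraday = "fitbit_heartrate_intraday",
  fitbit_heartrate_summary = "fitbit_heartrate_summary",
  fitbit_steps_intraday = "fitbit_steps_intraday",
  fitbit_steps_summary = "fitbit_steps_summary",
  fitbit_sleep_intraday = "fitbit_sleep_intraday",
  fitbit_sleep_summary = "fitbit_sleep_summary",
  fitbit_calories_intraday = "fitbit_calories_intraday",
  empatica_accelerometer = "empatica_accelerometer",
  empatica_heartrate = "empatica_heartrate",
  empatica_temperature = "empatica_temperature",
  empatica_electrodermal_activity = "empatica_electrodermal_activity",
  empatica_blood_volume_pulse = "empatica_blood_volume_pulse",
  empatica_inter_beat_interval = "empatica_inter_beat_interval")

.PHONE_YIELD_SENSORS <- c("calls", "sms", "screen", "battery", "light",
                          "accelerometer", "activity_recognition",
                          "applications_foreground", "bluetooth",
                          "wifi_connected", "wifi_visible", "conversation",
                          "keyboard", "locations")
.FITBIT_YIELD_SENSORS <- c("fitbit_heartrate_intraday", "fitbit_steps_intraday",
                           "fitbit_calories_intraday", "fitbit_sleep_intraday")

.DEFAULT_PARAMS <- list(
  hour_threshold = 0.5, accuracy_limit_m = 100, speed_threshold_kmh = 1,
  cluster_eps_m = 100, cluster_min_samples = 5, pause_min_duration_min = 5,
  hr_zones = c(90, 120, 160), steps_sedentary_threshold = 10,
  exertion_threshold = 12, bluetooth_own_share = 0.5,
  correlation_min_overlap = 30, correlation_method = "pearson",
  drop_empty_rows = FALSE, drop_truncated_episodes = FALSE,
  activity_gap_s = 300, keyboard_session_gap_s = 5)

#' Read and validate a pipeline configuration file
#'
#' The configuration is pure data (YAML): study file locations, the enabled
#' providers with parameters, and thresholds. Unknown top-level or parameter
#' keys are rejected so typos fail loudly. Relative paths are resolved
#' against the config file's directory.
#'
#' @param path YAML config file
#' @return a validated `pipeline_config` list
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("config file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  known_top <- c("study", "providers", "params", "workers", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  known_study <- c("name", "registry", "tz_history", "segments", "events",
                   "data_root", "output_root")
  unknown <- setdiff(names(raw$study), known_study)
  if (length(unknown)) {
    .stopf("unknown study key(s): %s", paste(unknown, collapse = ", "))
  }
  abspath <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^/", p)) p else file.path(base, p)
  }
  study <- raw$study
  for (k in c("registry", "tz_history", "segments", "events", "data_root",
              "output_root")) {
    study[[k]] <- abspath(study[[k]])
  }
  for (k in c("registry", "segments", "data_root")) {
    if (is.null(study[[k]]) || !file.exists(study[[k]])) {
      .stopf("config: study$%s missing or does not exist", k)
    }
  }
  providers <- raw$providers
  bad <- setdiff(names(providers), names(.PROVIDER_STREAM))
  if (length(bad)) .stopf("unknown provider sensor(s): %s",
                          paste(bad, collapse = ", "))
  params <- utils::modifyList(.DEFAULT_PARAMS, raw$params %||list% list())
  bad <- setdiff(names(params), names(.DEFAULT_PARAMS))
  if (length(bad)) .stopf("unknown param(s): %s", paste(bad, collapse = ", "))
  cfg <- list(study = study, providers = providers, params = params,
              workers = raw$workers %||% 1, seed = raw$seed %||% 0)
  class(cfg) <- "pipeline_config"
  cfg
}

`%||list%` <- function(a, b) if (is.null(a)) b else a

.enabled_sensors <- function(config) {
  en <- vapply(config$providers, function(p) isTRUE(p$enabled) ||
                 isTRUE(p), TRUE)
  names(config$providers)[en]
}

# catalog provider ids backing one enabled config sensor
.sensor_provider_ids <- function(sensor) {
  cat <- feature_catalog()
  unique(cat$provider_id[cat$sensor == sensor])
}

#' Plan the stage DAG for a configuration
#'
#' Stages: one feature stage per (participant, sensor, provider), a merge
#' stage per participant, one study merge, and one plots stage. Edges follow
#' data dependencies only; the graph is validated acyclic.
#'
#' @param config from [read_pipeline_config()]
#' @return list of stage nodes (id, kind, pid, provider_id, inputs, outputs,
#'   deps, params fingerprint)
#' @export
plan_pipeline <- function(config) {
  participants <- read_participant_registry(config$study$registry,
                                            config$study$tz_history)
  out_root <- config$study$output_root %||% file.path(dirname(config$study$registry), "output")
  sensors <- .enabled_sensors(config)
  stages <- list()
  pfp <- function(extra = NULL) {
    digest::digest(list(config$params, extra), algo = "md5")
  }
  stream_paths <- function(p, stream_sensor) {
    if (is.null(stream_sensor)) return(character(0))
    fs <- file.path(config$study$data_root, p$devices$device_id,
                    paste0(stream_sensor, ".csv"))
    fs[file.exists(fs)]
  }
  common_inputs <- c(config$study$registry, config$study$segments,
                     config$study$tz_history %||% character(0),
                     config$study$events %||% character(0))
  common_inputs <- common_inputs[file.exists(common_inputs)]
  for (p in participants) {
    pid_stage_ids <- character(0)
    for (sensor in sensors) {
      stream_sensor <- .PROVIDER_STREAM[[sensor]]
      inputs <- if (sensor == "data_yield") {
        unlist(lapply(.PHONE_YIELD_SENSORS, function(s) stream_paths(p, s)))
      } else if (sensor == "fitbit_data_yield") {
        unlist(lapply(.FITBIT_YIELD_SENSORS, function(s) stream_paths(p, s)))
      } else {
        stream_paths(p, stream_sensor)
      }
      for (prov_id in .sensor_provider_ids(sensor)) {
        sid <- sprintf("features/%s/%s", p$pid, prov_id)
        stages[[sid]] <- list(
          id = sid, kind = "features", pid = p$pid, provider_id = prov_id,
          inputs = unique(c(inputs, common_inputs)),
          outputs = file.path(out_root, p$pid, paste0(prov_id, ".csv")),
          deps = character(0), param_fp = pfp(prov_id))
        pid_stage_ids <- c(pid_stage_ids, sid)
      }
    }
    if (length(pid_stage_ids)) {
      mid <- sprintf("merge/%s", p$pid)
      stages[[mid]] <- list(
        id = mid, kind = "participant_merge", pid = p$pid, provider_id = NA,
        inputs = unlist(lapply(pid_stage_ids, function(s) stages[[s]]$outputs)),
        outputs = file.path(out_root, p$pid, "features.csv"),
        deps = pid_stage_ids, param_fp = pfp())
    }
  }
  merge_ids <- grep("^merge/", names(stages), value = TRUE)
  if (length(merge_ids)) {
    stages[["study_merge"]] <- list(
      id = "study_merge", kind = "study_merge", pid = NA, provider_id = NA,
      inputs = unlist(lapply(merge_ids, function(s) stages[[s]]$outputs)),
      outputs = file.path(out_root, "features_all.csv"),
      deps = merge_ids, param_fp = pfp())
    stages[["plots"]] <- list(
      id = "plots", kind = "plots", pid = NA, provider_id = NA,
      inputs = stages[["study_merge"]]$outputs,
      outputs = file.path(out_root, "reports",
                          paste0(plot_registry(), ".html")),
      deps = "study_merge", param_fp = pfp())
  }
  .check_acyclic(stages)
  structure(list(stages = stages, config = config, out_root = out_root),
            class = "pipeline_dag")
}

.check_acyclic <- function(stages) {
  state <- new.env()
  for (id in names(stages)) assign(id, 0L, envir = state)
  visit <- function(id) {
    s <- get(id, envir = state)
    if (s == 1L) .stopf("cycle detected at stage '%s'", id)
    if (s == 2L) return()
    assign(id, 1L, envir = state)
    for (d in stages[[id]]$deps) visit(d)
    assign(id, 2L, envir = state)
  }
  for (id in names(stages)) visit(id)
  invisible(TRUE)
}

.topo_levels <- function(stages) {
  level <- stats::setNames(rep(0L, length(stages)), names(stages))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (id in names(stages)) {
      deps <- stages[[id]]$deps
      if (length(deps)) {
        l <- max(level[deps]) + 1L
        if (l > level[id]) {
          level[id] <- l
          changed <- TRUE
        }
      }
    }
  }
  split(names(stages), level)
}

.hash_files <- function(paths) {
  paths <- sort(unique(paths[file.exists(paths)]))
  stats::setNames(vapply(paths, function(f) digest::digest(file = f,
                                                           algo = "md5"),
                         character(1)), paths)
}

.manifest_path <- function(out_root) file.path(out_root, "manifest.json")

.load_manifest <- function(out_root) {
  mp <- .manifest_path(out_root)
  if (file.exists(mp)) jsonlite::read_json(mp) else list()
}

.stage_current <- function(stage, manifest) {
  rec <- manifest[[stage$id]]
  if (is.null(rec)) return(FALSE)
  if (!all(file.exists(stage$outputs))) return(FALSE)
  if (!identical(rec$param_fp, stage$param_fp)) return(FALSE)
  now <- .hash_files(stage$inputs)
  old <- unlist(rec$input_hashes)
  identical(sort(names(now)), sort(names(old))) &&
    all(now[names(old)] == old)
}

#' Execute a planned pipeline incrementally
#'
#' A stage runs iff its recorded input hashes or parameter fingerprint
#' changed (or `force`); downstream stages of a re-run stage re-run. Stages
#' in the same dependency level may run on several workers; outputs are
#' deterministic and independent of worker count.
#'
#' @param dag from [plan_pipeline()]
#' @param workers parallel workers (default from config)
#' @param force re-run everything
#' @return execution report: data.table (stage, status) + `ok` attribute
#' @export
run_pipeline <- function(dag, workers = NULL, force = FALSE) {
  config <- dag$config
  workers <- workers %||% config$workers %||% 1
  out_root <- dag$out_root
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  manifest <- .load_manifest(out_root)
  stages <- dag$stages
  status <- stats::setNames(rep("pending", length(stages)), names(stages))
  reran <- character(0)
  for (lvl in .topo_levels(stages)) {
    todo <- character(0)
    for (id in lvl) {
      s <- stages[[id]]
      dep_failed <- any(status[s$deps] %in% c("failed", "skipped_failed"))
      if (dep_failed) {
        status[id] <- "skipped_failed"
        next
      }
      needs <- force || any(s$deps %in% reran) ||
        !.stage_current(s, manifest)
      if (needs) todo <- c(todo, id) else status[id] <- "skipped"
    }
    if (!length(todo)) next
    exec_one <- function(id) {
      tryCatch({
        .stage_exec(stages[[id]], config, out_root)
        "executed"
      }, error = function(e) {
        .log_stage(out_root, id, conditionMessage(e))
        "failed"
      })
    }
    res <- if (workers > 1 && length(todo) > 1 &&
                 .Platform$OS.type == "unix") {
      unlist(parallel::mclapply(todo, exec_one, mc.cores = workers))
    } else {
      vapply(todo, exec_one, character(1))
    }
    names(res) <- todo
    status[todo] <- res
    reran <- c(reran, todo[res == "executed"])
    for (id in todo[res == "executed"]) {
      manifest[[id]] <- list(param_fp = stages[[id]]$param_fp,
                             input_hashes = as.list(
                               .hash_files(stages[[id]]$inputs)))
    }
  }
  jsonlite::write_json(manifest, .manifest_path(out_root), auto_unbox = TRUE)
  report <- data.table(stage = names(status), status = unname(status))
  setattr(report, "ok", !any(status %in% c("failed", "skipped_failed")))
  report[]
}

.log_stage <- function(out_root, id, msg) {
  dir.create(file.path(out_root, "logs"), recursive = TRUE,
             showWarnings = FALSE)
  f <- file.path(out_root, "logs", paste0(gsub("/", "_", id), ".log"))
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
      file = f, append = TRUE)
}

# ---- stage execution ----

.participant_by_pid <- function(config, pid) {
  ps <- read_participant_registry(config$study$registry,
                                  config$study$tz_history)
  for (p in ps) if (p$pid == pid) return(p)
  .stopf("pid '%s' not in registry", pid)
}

.participant_instances <- function(config, participant) {
  specs <- read_segment_specs(config$study$segments)
  events <- NULL
  ev_path <- config$study$events
  if (!is.null(ev_path) && file.exists(ev_path)) events <- fread(ev_path)
  rbindlist(lapply(specs, function(sp) {
    ev <- events
    if (sp$kind == "event" && !is.na(sp$event_file)) {
      f <- file.path(dirname(config$study$segments), sp$event_file)
      if (file.exists(f)) ev <- fread(f)
    }
    expand_segments(sp, participant, ev)
  }))
}

.load_localized <- function(config, participant, stream_sensor) {
  paths <- file.path(config$study$data_root, participant$devices$device_id,
                     paste0(stream_sensor, ".csv"))
  paths <- paths[file.exists(paths)]
  st <- load_stream(participant, stream_sensor, paths)
  localize_stream(st, participant$tz_history)
}

.stage_exec <- function(stage, config, out_root) {
  switch(stage$kind,
    features = .exec_features(stage, config),
    participant_merge = .exec_participant_merge(stage),
    study_merge = .exec_study_merge(stage),
    plots = .exec_plots(stage, config, out_root),
    .stopf("unknown stage kind '%s'", stage$kind))
  invisible(TRUE)
}

.write_features <- function(fr, path, config) {
  if (isTRUE(config$params$drop_empty_rows)) {
    featcols <- setdiff(names(fr), c("pid", "label", "instance_id",
                                     "seg_start_wall", "seg_end_wall",
                                     "seg_start_utc_ms", "seg_end_utc_ms"))
    keep <- rowSums(!is.na(fr[, featcols, with = FALSE]) &
                      fr[, featcols, with = FALSE] != 0) > 0
    fr <- fr[keep]
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  fwrite(fr, path, dateTimeAs = "write.csv")
  invisible(path)
}

.exec_features <- function(stage, config) {
  p <- .participant_by_pid(config, stage$pid)
  instances <- .participant_instances(config, p)
  parts <- strsplit(stage$provider_id, ".", fixed = TRUE)[[1]]
  sensor <- parts[1]; provider <- parts[2]
  pp <- config$params
  fr <- .compute_provider(sensor, provider, p, instances, config, pp)
  .write_features(fr, stage$outputs, config)
}

.compute_provider <- function(sensor, provider, p, instances, config, pp) {
  loadL <- function(s) .load_localized(config, p, s)
  assignL <- function(st) assign_segments(st, instances)
  phone_platform <- if (nrow(p$devices[p$devices$device_class == "phone"])) {
    p$devices$platform[p$devices$device_class == "phone"][1]
  } else "android"
  if (sensor %in% c("calls_incoming", "calls_outgoing", "calls_missed")) {
    a <- assignL(loadL("calls"))
    return(call_features(a, instances, sub("calls_", "", sensor)))
  }
  switch(sensor,
    sms = sms_features(assignL(loadL("sms")), instances),
    screen = {
      st <- loadL("screen")
      ep <- screen_episodes(st, phone_platform)
      if (isTRUE(pp$drop_truncated_episodes)) ep <- ep[truncated == FALSE]
      screen_features(split_on_boundaries(ep, instances), instances)
    },
    light = generic_numeric_features(assignL(loadL("light")), instances),
    battery = {
      ep <- battery_episodes(loadL("battery"))
      battery_features(split_on_boundaries(ep, instances), instances)
    },
    data_yield = {
      rows <- rbindlist(lapply(.PHONE_YIELD_SENSORS, function(s) {
        st <- loadL(s)
        if (nrow(st)) st[, .(timestamp)] else NULL
      }))
      a <- assignL(localize_stream(
        if (nrow(rows)) rows else data.table(timestamp = numeric(0)),
        p$tz_history))
      data_yield_features(a, instances, pp$hour_threshold, "data_yield")
    },
    activity_recognition = {
      st <- loadL("activity_recognition")
      ep <- activity_episodes(st, pp$activity_gap_s)
      activity_features(assignL(st), split_on_boundaries(ep, instances),
                        instances)
    },
    applications_foreground =
      app_foreground_features(assignL(loadL("applications_foreground")),
                              instances),
    wifi_connected = wifi_features(assignL(loadL("wifi_connected")),
                                   instances, "wifi_connected"),
    wifi_visible = wifi_features(assignL(loadL("wifi_visible")),
                                 instances, "wifi_visible"),
    bluetooth = {
      a <- assignL(loadL("bluetooth"))
      if (provider == "doryab") {
        bluetooth_doryab_features(a, instances, pp$bluetooth_own_share)
      } else bluetooth_features(a, instances)
    },
    conversation = conversation_features(assignL(loadL("conversation")),
                                         instances),
    keyboard = keyboard_features(assignL(loadL("keyboard")), instances,
                                 pp$keyboard_session_gap_s),
    accelerometer = {
      a <- assignL(loadL("accelerometer"))
      if (provider == "panda") {
        accelerometer_exertion_features(a, instances, pp$exertion_threshold)
      } else accelerometer_features(a, instances, "accelerometer")
    },
    locations = {
      st <- filter_accuracy(loadL("locations"), pp$accuracy_limit_m)
      st <- detect_stationary(st, pp$speed_threshold_kmh)
      cl <- cluster_places(st[st$stationary == TRUE], pp$cluster_eps_m,
                           pp$cluster_min_samples)
      lab <- cl$points[, .(timestamp, cluster)]
      st2 <- lab[st, on = "timestamp"]
      st2[is.na(cluster), cluster := 0L]
      a <- assignL(st2)
      if (provider == "barnett") {
        trajectory_provider_features(a, cl$clusters, instances,
                                     pp$pause_min_duration_min)
      } else {
        cluster_provider_features(a, cl$clusters, instances)
      }
    },
    fitbit_data_yield = {
      rows <- rbindlist(lapply(.FITBIT_YIELD_SENSORS, function(s) {
        st <- loadL(s)
        if (nrow(st)) st[, .(timestamp)] else NULL
      }))
      a <- assignL(localize_stream(
        if (nrow(rows)) rows else data.table(timestamp = numeric(0)),
        p$tz_history))
      data_yield_features(a, instances, pp$hour_threshold,
                          "fitbit_data_yield")
    },
    fitbit_heartrate_intraday =
      heart_rate_intraday_features(assignL(loadL(sensor)), instances,
                                   heart_rate_zones(unlist(pp$hr_zones))),
    fitbit_heartrate_summary =
      heartrate_summary_features(assignL(loadL(sensor)), instances),
    fitbit_steps_intraday =
      steps_intraday_features(assignL(loadL(sensor)), instances,
                              pp$steps_sedentary_threshold),
    fitbit_steps_summary =
      steps_summary_features(assignL(loadL(sensor)), instances),
    fitbit_calories_intraday =
      calories_intraday_features(assignL(loadL(sensor)), instances),
    fitbit_sleep_summary =
      sleep_summary_features(assignL(loadL(sensor)), instances),
    fitbit_sleep_intraday = {
      ep <- sleep_episodes(loadL(sensor))
      frags <- split_on_boundaries(ep, instances)
      if (provider == "price") {
        sleep_intraday_price_features(frags, instances)
      } else sleep_intraday_features(frags, instances)
    },
    empatica_accelerometer =
      accelerometer_features(assignL(loadL(sensor)), instances,
                             "empatica_accelerometer"),
    {
      if (!sensor %in% names(.EMPATICA_VALUE)) {
        .stopf("no compute rule for sensor '%s'", sensor)
      }
      empatica_stream_features(assignL(loadL(sensor)), instances, sensor)
    })
}

.exec_participant_merge <- function(stage) {
  metas <- c("pid", "label", "instance_id", "seg_start_wall", "seg_end_wall",
             "seg_start_utc_ms", "seg_end_utc_ms")
  pieces <- lapply(sort(stage$inputs[file.exists(stage$inputs)]), fread)
  pieces <- pieces[vapply(pieces, nrow, 1L) > 0]
  if (!length(pieces)) {
    fwrite(data.table(), stage$outputs)
    return(invisible())
  }
  merged <- Reduce(function(a, b) {
    merge(a, b, by = intersect(metas, intersect(names(a), names(b))),
          all = TRUE)
  }, pieces)
  setorder(merged, instance_id)
  fwrite(merged, stage$outputs)
}

.exec_study_merge <- function(stage) {
  pieces <- lapply(sort(stage$inputs[file.exists(stage$inputs)]), fread)
  pieces <- pieces[vapply(pieces, function(x) nrow(x) > 0, TRUE)]
  merged <- rbindlist(pieces, use.names = TRUE, fill = TRUE)
  if (nrow(merged)) setorder(merged, pid, instance_id)
  fwrite(merged, stage$outputs)
}

.exec_plots <- function(stage, config, out_root) {
  dir.create(file.path(out_root, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  feats <- fread(stage$inputs[1])
  ycol <- "rapids_data_yield_ratiovalidyieldedminutes"
  ydt <- if (nrow(feats) && ycol %in% names(feats)) feats else NULL
  rp <- function(id) file.path(out_root, "reports", paste0(id, ".html"))
  plot_yield_histogram(ydt, rp("yield_histogram"), ycol)
  plot_yield_heatmap_participant(ydt, rp("yield_heatmap_participant"), ycol)
  counts <- .sensed_row_counts(config)
  plot_sensed_rows_heatmap(counts, rp("sensed_rows_heatmap"))
  plot_yield_per_segment_heatmap(ydt, rp("yield_per_segment_heatmap"), ycol)
  plot_feature_correlation_heatmap(feats, rp("feature_correlation_heatmap"),
                                   config$params$correlation_min_overlap,
                                   config$params$correlation_method)
}

.sensed_row_counts <- function(config) {
  ps <- read_participant_registry(config$study$registry,
                                  config$study$tz_history)
  rbindlist(lapply(ps, function(p) {
    rbindlist(lapply(supported_sensors(), function(s) {
      paths <- file.path(config$study$data_root, p$devices$device_id,
                         paste0(s, ".csv"))
      paths <- paths[file.exists(paths)]
      if (!length(paths)) return(NULL)
      n <- sum(vapply(paths, function(f) nrow(fread(f, select = 1L)),
                      1L))
      data.table(pid = p$pid, sensor = s, n_rows = n)
    }))
  }))
}

#' Plan and run a study pipeline from a config file
#' @param config_path YAML config
#' @param workers parallel workers (overrides config)
#' @param force re-run all stages
#' @return execution report from [run_pipeline()]
#' @export
run_study <- function(config_path, workers = NULL, force = FALSE) {
  config <- read_pipeline_config(config_path)
  dag <- plan_pipeline(config)
  run_pipeline(dag, workers = workers, force = force)
}
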