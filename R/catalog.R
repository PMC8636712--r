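# The feature catalog: every provider, its sensor, device class, and ordered
# feature-name list. Per-sensor feature COUNTS are the published conformance
# surface; member names are this package's documented conventions (see the
# methods vignette). Counts are asserted at build time so a drifting catalog
# fails immediately rather than at analysis time.

.stat5 <- function(stem) paste0(c("max", "min", "avg", "median", "std"), stem)
.stat9 <- function(stem) {
  paste0(c("max", "min", "avg", "median", "mode", "std",
           "diffmaxmode", "diffminmode", "entropy"), stem)
}
.dur6 <- function(suffix = "") {
  paste0(c("countepisode", "sumduration", "maxduration", "minduration",
           "avgduration", "stdduration"), suffix)
}

.catalog_build <- function() {
  call_full <- c("count", "distinctcontacts", "meanduration", "sumduration",
                 "minduration", "maxduration", "stdduration", "modeduration",
                 "entropyduration", "timefirstcall", "timelastcall",
                 "countmostfrequentcontact")
  call_missed <- c("count", "distinctcontacts", "timefirstcall",
                   "timelastcall", "countmostfrequentcontact")
  sms5 <- function(kind) paste0(c("count", "distinctcontacts", "timefirstsms",
                                  "timelastsms", "countmostfrequentcontact"),
                                kind)
  wifi3 <- c("countscans", "uniquedevices", "countscansmostuniquedevice")
  bt_stat9 <- c("countscans", "uniquedevices", "meanscans", "stdscans",
                "modescans", "maxscans", "minscans",
                "countscansmostfrequentdevice", "countscansleastfrequentdevice")
  conv <- c(paste0("minutes", c("silence", "noise", "voice", "unknown")),
            "countconversation",
            paste0(c("sum", "max", "min", "avg", "sd"), "conversationduration"),
            "timefirstconversation", "timelastconversation",
            paste0(c("sum", "avg", "sd", "min", "max"), "energy", "noise"),
            paste0(c("sum", "avg", "sd", "min", "max"), "energy", "voice"),
            paste0(c("silence", "noise", "voice", "unknown"), "sensedfraction"),
            paste0(c("silence", "noise", "voice", "unknown"), "expectedfraction"))
  keyboard <- c("sessioncount", "averagesessionlength", "maxtextlength",
                "totalkeyboardtouches", "averageinterkeydelay",
                "stdinterkeydelay", "changeintextlengthlessthanminusone",
                "changeintextlengthequaltominusone",
                "changeintextlengthequaltoone", "changeintextlengthmorethanone")
  cluster18 <- c("locationvariance", "loglocationvariance", "totaldistance",
                 "avgspeed", "circadianmovement", "numberofsignificantplaces",
                 "numberlocationtransitions", "radiusgyration",
                 "timeattop1location", "timeattop2location", "timeattop3location",
                 "outlierstimepercent", "maxlengthstayatclusters",
                 "minlengthstayatclusters", "avglengthstayatclusters",
                 "stdlengthstayatclusters", "locationentropy",
                 "normalizedlocationentropy")
  traj16 <- c("hometime", "disttravelled", "rog", "maxdiam", "maxhomedist",
              "siglocsvisited", "avgflightlen", "stdflightlen", "avgflightdur",
              "stdflightdur", "probpause", "siglocentropy", "minsmissing",
              "circdnrtn", "wkenddayrtn", "minutesdataused")
  hr_zones <- c("outofrange", "fatburn", "cardio", "peak")
  cal_levels <- c("sedentary", "lightlyactive", "fairlyactive", "veryactive")
  cal22 <- c(unlist(lapply(cal_levels, function(l) {
    paste0(c("minutes", "calories", "countepisode", "maxdurationepisode",
             "avgdurationepisode"), l)
  })), "sumcalories", "avgcaloriesperminute")
  hrsum37 <- c(.stat9("restinghr"),
               unlist(lapply(hr_zones, function(z) {
                 paste0(c("summinutes", "maxminutes", "minminutes",
                          "avgminutes", "stdminutes", "sumcalories",
                          "avgcalories"), z, "zone")
               })))
  sleep_types <- c("main", "nap", "all")
  sleepsum36 <- unlist(lapply(sleep_types, function(ty) {
    paste0(c("countepisode", "sumdurationinbed", "sumdurationasleep",
             "sumdurationawake", "avgefficiency", "maxdurationasleep",
             "mindurationasleep", "avgdurationasleep", "stddurationasleep",
             "avgdurationawake", "firstbedtime", "lastwaketime"), ty)
  }))
  stages <- c("awake", "light", "deep", "rem", "asleep")
  sleepintra21 <- c(unlist(lapply(stages, function(s) {
    paste0(c("countepisode", "sumduration", "maxduration", "avgduration"), s)
  })), "ratioasleepinbed")
  sleepintra13 <- c(.dur6("all"),
                    paste0("ratio", c("awake", "light", "deep", "rem"), "inbed"),
                    "firstbedtime", "lastwaketime", "countdaysleep")

  reg <- list(
    # -- phone --
    list("phone", "calls_incoming", "rapids", call_full, 12L),
    list("phone", "calls_outgoing", "rapids", call_full, 12L),
    list("phone", "calls_missed", "rapids", call_missed, 5L),
    list("phone", "sms", "rapids", c(sms5("sent"), sms5("received")), 10L),
    list("phone", "screen", "rapids",
         c("countepisode", "sumduration", "maxduration", "minduration",
           "avgduration", "stdduration", "firstuseafter"), 7L),
    list("phone", "light", "rapids",
         c("count", "maxlux", "minlux", "avglux", "medianlux", "stdlux"), 6L),
    list("phone", "battery", "rapids",
         c("countdischarge", "sumdurationdischarge", "countcharge",
           "sumdurationcharge", "avgconsumptionrate", "maxconsumptionrate"), 6L),
    list("phone", "data_yield", "rapids",
         c("ratiovalidyieldedminutes", "ratiovalidyieldedhours"), 2L),
    list("phone", "activity_recognition", "rapids",
         c("count", "mostcommonactivity", "countuniqueactivities",
           "durationstationary", "durationmobile", "durationvehicle"), 6L),
    list("phone", "applications_foreground", "rapids",
         c("count", "timeoffirstuse", "timeoflastuse", "frequencyentropy"), 4L),
    list("phone", "wifi_connected", "rapids", wifi3, 3L),
    list("phone", "wifi_visible", "rapids", wifi3, 3L),
    list("phone", "bluetooth", "rapids", wifi3, 3L),
    list("phone", "bluetooth", "doryab",
         as.vector(t(outer(c("all", "own", "others"), bt_stat9,
                           function(a, b) paste0(b, a)))), 27L),
    list("phone", "conversation", "rapids", conv, 30L),
    list("phone", "keyboard", "rapids", keyboard, 10L),
    list("phone", "accelerometer", "rapids", .stat5("magnitude"), 5L),
    list("phone", "accelerometer", "panda",
         .dur6("exertionalactivityepisode"), 6L),
    list("phone", "locations", "doryab", cluster18, 18L),
    list("phone", "locations", "barnett", traj16, 16L),
    # -- fitbit --
    list("fitbit", "fitbit_data_yield", "rapids",
         c("ratiovalidyieldedminutes", "ratiovalidyieldedhours"), 2L),
    list("fitbit", "fitbit_calories_intraday", "rapids", cal22, 22L),
    list("fitbit", "fitbit_heartrate_summary", "rapids", hrsum37, 37L),
    list("fitbit", "fitbit_heartrate_intraday", "rapids",
         c(.stat9("hr"), paste0("minuteson", hr_zones, "zone")), 13L),
    list("fitbit", "fitbit_steps_summary", "rapids",
         paste0(c("max", "min", "avg", "median", "std"), "sumsteps"), 5L),
    list("fitbit", "fitbit_steps_intraday", "rapids",
         c("sumsteps", .stat5("steps")[c(1, 2, 3, 5)],
           .dur6("sedentarybout"), .dur6("activebout")), 17L),
    list("fitbit", "fitbit_sleep_summary", "rapids", sleepsum36, 36L),
    list("fitbit", "fitbit_sleep_intraday", "rapids", sleepintra21, 21L),
    list("fitbit", "fitbit_sleep_intraday", "price", sleepintra13, 13L),
    # -- empatica --
    list("empatica", "empatica_accelerometer", "rapids",
         .stat5("magnitude"), 5L),
    list("empatica", "empatica_heartrate", "rapids", .stat9("hr"), 9L),
    list("empatica", "empatica_temperature", "rapids", .stat9("temp"), 9L),
    list("empatica", "empatica_electrodermal_activity", "rapids",
         .stat9("eda"), 9L),
    list("empatica", "empatica_blood_volume_pulse", "rapids", .stat9("bvp"), 9L),
    list("empatica", "empatica_inter_beat_interval", "rapids", .stat9("ibi"), 9L)
  )
  rows <- lapply(reg, function(r) {
    if (length(r[[4]]) != r[[5]] || anyDuplicated(r[[4]])) {
      .stopf("catalog defect: %s/%s registers %d names, contract is %d",
             r[[2]], r[[3]], length(r[[4]]), r[[5]])
    }
    data.table(device_class = r[[1]], sensor = r[[2]], provider = r[[3]],
               feature = r[[4]])
  })
  cat <- rbindlist(rows)
  cat[, provider_id := paste(sensor, provider, sep = ".")]
  cat[, qualified := paste(provider, sensor, feature, sep = "_")]
  if (nrow(cat) != 407L) {
    .stopf("catalog defect: %d features registered, contract is 407", nrow(cat))
  }
  cat
}

.catalog_env <- new.env(parent = emptyenv())

#' The full behavioral-feature catalog
#'
#' Returns the registry of every feature provider: one row per feature with
#' its sensor, device class, provider, and globally qualified name
#' (`provider_sensor_feature`). The catalog is fixed at 407 features across
#' phone, Fitbit, and Empatica device classes and is validated against the
#' published per-sensor counts when first built.
#'
#' @return A `data.table` with columns `device_class`, `sensor`, `provider`,
#'   `feature`, `provider_id`, `qualified`.
#' @export
#' @examples
#' nrow(feature_catalog())  # 407
feature_catalog <- function() {
  if (is.null(.catalog_env$catalog)) .catalog_env$catalog <- .catalog_build()
  copy(.catalog_env$catalog)
}

#' Count registered features in a scope
#'
#' @param scope `"all"`, a device class (`"phone"`, `"fitbit"`, `"empatica"`),
#'   a sensor name (e.g. `"calls_incoming"`), or a provider id
#'   (`"<sensor>.<provider>"`, e.g. `"locations.doryab"`).
#' @return integer count of distinct feature names in scope
#' @export
#' @examples
#' catalog_count("all")             # 407
#' catalog_count("calls_incoming")  # 12
catalog_count <- function(scope = "all") {
  cat <- feature_catalog()
  if (identical(scope, "all")) return(nrow(cat))
  if (scope %in% cat$device_class) return(nrow(cat[cat$device_class == scope]))
  if (scope %in% cat$sensor) return(nrow(cat[cat$sensor == scope]))
  if (scope %in% cat$provider_id) return(nrow(cat[cat$provider_id == scope]))
  .stopf("unknown catalog scope '%s'", scope)
}

#' Feature names registered for one provider
#' @param sensor sensor name
#' @param provider provider name (default "rapids")
#' @return character vector of feature names, in registry order
#' @export
provider_features <- function(sensor, provider = "rapids") {
  cat <- feature_catalog()
  sel <- cat$sensor == sensor & cat$provider == provider
  out <- cat[which(sel)]
  if (!nrow(out)) .stopf("no provider '%s' for sensor '%s'", provider, sensor)
  out$feature
}
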