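# Mobility features: the cluster-based provider (significant places,
# location variance/entropy, radius of gyration, circadian movement) and the
# trajectory provider (flights/pauses, home time, routine indices).
#
# Significant places are density-based clusters (DBSCAN on great-circle
# distance) over STATIONARY points of a participant's whole history, so
# cluster identities are stable across segments. Dwell time at a point is
# the gap to the next point, capped so sampling holes do not inflate stays.

.EARTH_RADIUS_M <- 6371000

#' Great-circle distance in meters (haversine, Earth radius 6,371,000 m)
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized)
#' @return distance in meters
#' @export
#' @examples
#' haversine_m(0, 0, 0, 180)  # half circumference, ~20,015 km
haversine_m <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * .EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Filter location rows by reported accuracy
#' @param points location table with `accuracy` column (meters)
#' @param max_accuracy_m exclusion threshold, default 100 m
#' @export
filter_accuracy <- function(points, max_accuracy_m = 100) {
  if (!nrow(points) || !"accuracy" %in% names(points)) return(points)
  points[is.na(accuracy) | accuracy <= max_accuracy_m]
}

#' Label location points stationary or moving by segment speed
#'
#' A point is moving when the speed from the previous point exceeds
#' `speed_threshold_kmh` (default 1 km/h); the first point (and any point
#' after a zero-length time step) is stationary.
#' @param points time-sorted location table (timestamp, double_latitude,
#'   double_longitude)
#' @param speed_threshold_kmh threshold in km/h
#' @return the table with logical `stationary` and numeric `speed_kmh` added
#' @export
detect_stationary <- function(points, speed_threshold_kmh = 1) {
  p <- copy(as.data.table(points))
  if (!nrow(p)) {
    p[, `:=`(stationary = logical(0), speed_kmh = numeric(0))]
    return(p[])
  }
  setorder(p, timestamp)
  n <- nrow(p)
  if (n == 1L) {
    p[, `:=`(stationary = TRUE, speed_kmh = 0)]
    return(p[])
  }
  d_m <- haversine_m(p$double_latitude[-n], p$double_longitude[-n],
                     p$double_latitude[-1], p$double_longitude[-1])
  dt_h <- diff(p$timestamp) / 3.6e6
  spd <- ifelse(dt_h > 0, (d_m / 1000) / dt_h, 0)
  p[, speed_kmh := c(0, spd)]
  p[, stationary := speed_kmh <= speed_threshold_kmh]
  p[]
}

# DBSCAN over haversine distances; returns integer labels (0 = noise).
.dbscan_haversine <- function(lat, lon, eps_m, min_samples) {
  n <- length(lat)
  if (!n) return(integer(0))
  # neighbor lists, chunked to bound memory at ~chunk*n doubles
  chunk <- max(1L, floor(4e6 / n))
  neighbors <- vector("list", n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    d <- outer(idx, seq_len(n), function(i, j) {
      haversine_m(lat[i], lon[i], lat[j], lon[j])
    })
    for (k in seq_along(idx)) {
      neighbors[[idx[k]]] <- which(d[k, ] <= eps_m)
    }
  }
  core <- vapply(neighbors, length, 1L) >= min_samples
  labels <- integer(n)           # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (core[j]) {
        nb <- neighbors[[j]]
        fresh <- nb[labels[nb] == 0L]
        labels[fresh] <- cl
        queue <- c(queue, fresh[core[fresh]])
      }
    }
  }
  labels
}

# forward dwell minutes per point (gap to next point, capped)
.dwell_minutes <- function(ts_ms, cap_min = 10) {
  n <- length(ts_ms)
  if (!n) return(numeric(0))
  gaps <- c(diff(ts_ms) / 60000, 1)
  pmin(gaps, cap_min)
}

#' Cluster stationary points into significant places
#'
#' Density-based clustering (DBSCAN) on great-circle distance over the
#' participant's stationary points. Clusters are re-labeled by dwell time:
#' label 1 has the most dwell (the home candidate); noise points keep
#' label 0.
#'
#' @param points stationary location table (timestamp, double_latitude,
#'   double_longitude), whole-study
#' @param eps_m DBSCAN radius in meters (default 100)
#' @param min_samples minimum neighborhood size for a core point (default 5)
#' @return list: `points` (input + `cluster` column), `clusters` (data.table
#'   cluster/centroid_lat/centroid_lon/dwell_minutes/n_points, dwell-ranked)
#' @export
cluster_places <- function(points, eps_m = 100, min_samples = 5) {
  p <- copy(as.data.table(points))
  if (!nrow(p)) {
    p[, cluster := integer(0)]
    return(list(points = p,
                clusters = data.table(cluster = integer(0),
                                      centroid_lat = numeric(0),
                                      centroid_lon = numeric(0),
                                      dwell_minutes = numeric(0),
                                      n_points = integer(0))))
  }
  setorder(p, timestamp)
  raw <- .dbscan_haversine(p$double_latitude, p$double_longitude,
                           eps_m, min_samples)
  p[, cluster := raw]
  p[, .dwell := .dwell_minutes(timestamp)]
  summ <- p[cluster > 0, .(centroid_lat = mean(double_latitude),
                           centroid_lon = mean(double_longitude),
                           dwell_minutes = sum(.dwell), n_points = .N),
            by = cluster]
  setorder(summ, -dwell_minutes, cluster)
  if (nrow(summ)) {
    relabel <- stats::setNames(seq_len(nrow(summ)), summ$cluster)
    p[cluster > 0, cluster := relabel[as.character(cluster)]]
    summ[, cluster := seq_len(.N)]
  }
  p[, .dwell := NULL]
  list(points = p[], clusters = summ)
}

# ---- Lomb-Scargle ----

#' Least-squares (Lomb-Scargle) normalized periodogram
#'
#' Classic Lomb normalization: power of a pure sinusoid sampled without noise
#' grows with n/2 after division by the series variance.
#' @param t_s sample times in seconds (irregular allowed)
#' @param y values
#' @param freqs_hz frequencies to evaluate
#' @return numeric vector of normalized powers
#' @export
lomb_scargle <- function(t_s, y, freqs_hz) {
  ok <- is.finite(t_s) & is.finite(y)
  t_s <- t_s[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3L || stats::var(y) == 0) return(rep(NA_real_, length(freqs_hz)))
  yc <- y - mean(y)
  vy <- stats::var(y)
  vapply(freqs_hz, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t_s)), sum(cos(2 * w * t_s))) / (2 * w)
    ct <- cos(w * (t_s - tau)); st <- sin(w * (t_s - tau))
    0.5 / vy * (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Circadian movement of a location trace
#'
#' log10 of the mean normalized spectral power of the latitude and longitude
#' series in the 23.5-24.5 h period band of a least-squares periodogram.
#' Requires at least `min_points` samples, else NA.
#' @param points location table
#' @param n_freq number of evaluated band frequencies
#' @param min_points minimum samples
#' @export
circadian_movement <- function(points, n_freq = 40, min_points = 20) {
  if (nrow(points) < min_points) return(NA_real_)
  periods_h <- seq(23.5, 24.5, length.out = n_freq)
  freqs <- 1 / (periods_h * 3600)
  t_s <- points$timestamp / 1000
  p_lat <- lomb_scargle(t_s, points$double_latitude, freqs)
  p_lon <- lomb_scargle(t_s, points$double_longitude, freqs)
  tot <- mean(p_lat, na.rm = TRUE) + mean(p_lon, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  log10(tot)
}

# radius of gyration over dwell-weighted cluster centroids
.radius_gyration <- function(cl_lat, cl_lon, weights) {
  tot <- sum(weights)
  if (!length(weights) || tot <= 0) return(0)
  wlat <- sum(cl_lat * weights) / tot
  wlon <- sum(cl_lon * weights) / tot
  d <- haversine_m(cl_lat, cl_lon, wlat, wlon)
  sqrt(sum(weights * d^2) / tot)
}

#' Cluster-based location features (18 per segment instance)
#'
#' Computed per instance over that instance's accuracy-filtered points, with
#' cluster identities taken from whole-study clustering so "top-K place"
#' features stay comparable across segments.
#'
#' @param assigned localized location rows assigned to instances, carrying a
#'   `cluster` column from [cluster_places()] (0 = noise)
#' @param clusters cluster summary from [cluster_places()]
#' @param instances instance table
#' @return FeatureRow table
#' @export
cluster_provider_features <- function(assigned, clusters, instances) {
  stats <- if (nrow(assigned)) assigned[order(timestamp), {
    lat <- double_latitude; lon <- double_longitude
    n <- .N
    dwell <- .dwell_minutes(timestamp)
    lv <- if (n >= 2) stats::var(lat) + stats::var(lon) else NA_real_
    dists <- if (n >= 2) haversine_m(lat[-n], lon[-n], lat[-1], lon[-1]) else
      numeric(0)
    dt_h <- if (n >= 2) diff(timestamp) / 3.6e6 else numeric(0)
    spd <- (dists / 1000)[dt_h > 0] / dt_h[dt_h > 0]
    cl <- cluster
    clustered <- cl > 0
    visits <- cl[clustered]
    dwell_by_cl <- tapply(dwell[clustered], visits, sum)
    k <- length(dwell_by_cl)
    trans <- if (sum(clustered) >= 2) {
      v <- cl[clustered]
      sum(v[-1] != head(v, -1))
    } else 0
    # maximal stays at one cluster
    stays <- if (sum(clustered)) {
      g <- cumsum(c(TRUE, visits[-1] != head(visits, -1)))
      as.numeric(tapply(dwell[clustered], g, sum))
    } else numeric(0)
    rog_w <- if (k) {
      ids <- as.integer(names(dwell_by_cl))
      cc <- clusters[match(ids, cluster)]
      .radius_gyration(cc$centroid_lat, cc$centroid_lon,
                       as.numeric(dwell_by_cl))
    } else 0
    top_time <- function(rank) {
      if (as.character(rank) %in% names(dwell_by_cl))
        as.numeric(dwell_by_cl[[as.character(rank)]]) else 0
    }
    ent <- .shannon(as.numeric(dwell_by_cl))
    list(
      locationvariance = lv,
      loglocationvariance = if (is.finite(lv) && lv > 0) log10(lv) else NA_real_,
      totaldistance = sum(dists),
      avgspeed = if (length(spd)) mean(spd) else NA_real_,
      circadianmovement = circadian_movement(.SD),
      numberofsignificantplaces = as.numeric(k),
      numberlocationtransitions = as.numeric(trans),
      radiusgyration = rog_w,
      timeattop1location = top_time(1), timeattop2location = top_time(2),
      timeattop3location = top_time(3),
      outlierstimepercent = if (sum(dwell) > 0)
        100 * sum(dwell[!clustered]) / sum(dwell) else NA_real_,
      maxlengthstayatclusters = if (length(stays)) max(stays) else 0,
      minlengthstayatclusters = if (length(stays)) min(stays) else 0,
      avglengthstayatclusters = if (length(stays)) mean(stays) else 0,
      stdlengthstayatclusters = .sd_or_na(stays),
      locationentropy = ent,
      normalizedlocationentropy = if (k > 1) ent / log(k) else NA_real_)
  }, by = instance_id] else NULL
  .emit_features(instances, stats, "locations", "doryab",
                 zero_fill = c("numberofsignificantplaces",
                               "numberlocationtransitions", "totaldistance",
                               "timeattop1location", "timeattop2location",
                               "timeattop3location"))
}

# decompose one instance's points into pauses and flights
.flights_pauses <- function(p, pause_min_duration_min = 5) {
  # p: time-sorted with stationary flag
  n <- nrow(p)
  if (n < 2) {
    return(list(flights = data.table(length_m = numeric(0),
                                     duration_min = numeric(0)),
                pause_min = if (n == 1) 0 else 0))
  }
  runs <- rle(p$stationary)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  seg <- data.table(start = starts, end = ends, stationary = runs$values)
  seg[, dur_min := (p$timestamp[end] - p$timestamp[start]) / 60000]
  # short stationary runs are absorbed into movement
  seg[, is_pause := stationary & dur_min >= pause_min_duration_min]
  flights <- seg[!(is_pause)]
  fl <- flights[, {
    lens <- vapply(seq_len(.N), function(i) {
      i0 <- start[i]; i1 <- end[i]
      if (i1 <= i0) return(0)
      idx <- i0:i1
      sum(haversine_m(p$double_latitude[head(idx, -1)],
                      p$double_longitude[head(idx, -1)],
                      p$double_latitude[idx[-1]],
                      p$double_longitude[idx[-1]]))
    }, numeric(1))
    .(length_m = lens, duration_min = dur_min)
  }]
  fl <- fl[length_m > 0]
  list(flights = fl, pause_min = sum(seg$dur_min[seg$is_pause]))
}

.day_dwell_cosine <- function(dates, clusters_vec, dwell, which_days = NULL) {
  dt <- data.table(d = dates, c = clusters_vec, w = dwell)
  if (!is.null(which_days)) dt <- dt[d %in% which_days]
  days <- unique(dt$d)
  if (length(days) < 2) return(NA_real_)
  cls <- sort(unique(dt$c))
  vecs <- lapply(days, function(dd) {
    v <- dt[d == dd, .(w = sum(w)), by = c]
    out <- stats::setNames(rep(0, length(cls)), cls)
    out[as.character(v$c)] <- v$w
    out
  })
  sims <- c()
  for (i in seq_along(vecs)) for (j in seq_along(vecs)) {
    if (j <= i) next
    a <- vecs[[i]]; b <- vecs[[j]]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na > 0 && nb > 0) sims <- c(sims, sum(a * b) / (na * nb))
  }
  if (!length(sims)) return(NA_real_)
  mean(sims)
}

#' Trajectory-based location features (16 per segment instance)
#'
#' Decomposes each instance's trace into flights (movement legs) and pauses
#' (stationary dwells of at least `pause_min_duration_min`). Home is the
#' cluster with the most whole-study dwell between 00:00 and 06:00 local
#' time. Routine indices are mean pairwise cosine similarities between daily
#' cluster-dwell vectors (all day pairs for `circdnrtn`; same-type pairs,
#' weekend with weekend and weekday with weekday, for `wkenddayrtn`); both
#' need at least two (matching) days in the segment, else NA.
#'
#' @param assigned assigned location rows with `cluster`, `stationary`,
#'   `local_wall`, `local_date` columns
#' @param clusters cluster summary from [cluster_places()]
#' @param instances instance table
#' @param pause_min_duration_min minimum pause duration (minutes)
#' @param max_diam_points subsample cap for the pairwise diameter
#' @export
trajectory_provider_features <- function(assigned, clusters, instances,
                                         pause_min_duration_min = 5,
                                         max_diam_points = 500) {
  home_id <- NA_integer_
  if (nrow(assigned)) {
    night <- assigned[cluster > 0 &
                        .minutes_since_midnight(local_wall) < 360]
    if (nrow(night)) {
      nd <- night[, .(w = sum(.dwell_minutes(timestamp))), by = cluster]
      home_id <- nd$cluster[which.max(nd$w)]
    } else if (nrow(clusters)) home_id <- clusters$cluster[1]
  }
  home <- if (!is.na(home_id)) clusters[cluster == home_id] else NULL
  stats <- if (nrow(assigned)) assigned[order(timestamp), {
    dwell <- .dwell_minutes(timestamp)
    seg_min <- (seg_end_utc_ms[1] - seg_start_utc_ms[1]) / 60000
    minute_bins <- data.table::uniqueN(floor(timestamp / 60000))
    fp <- .flights_pauses(.SD, pause_min_duration_min)
    fl <- fp$flights
    covered_min <- (max(timestamp) - min(timestamp)) / 60000
    idx <- if (.N > max_diam_points)
      round(seq(1, .N, length.out = max_diam_points)) else seq_len(.N)
    dm <- 0
    for (i in idx) {
      dm <- max(dm, max(haversine_m(double_latitude[i], double_longitude[i],
                                    double_latitude[idx],
                                    double_longitude[idx])))
    }
    dwell_by_cl <- tapply(dwell[cluster > 0], cluster[cluster > 0], sum)
    rog_w <- if (length(dwell_by_cl)) {
      ids <- as.integer(names(dwell_by_cl))
      cc <- clusters[match(ids, cluster)]
      .radius_gyration(cc$centroid_lat, cc$centroid_lon,
                       as.numeric(dwell_by_cl))
    } else 0
    list(
      hometime = if (!is.na(home_id))
        sum(dwell[cluster == home_id]) else NA_real_,
      disttravelled = sum(fl$length_m),
      rog = rog_w,
      maxdiam = dm,
      maxhomedist = if (!is.null(home) && nrow(home))
        max(haversine_m(double_latitude, double_longitude,
                        home$centroid_lat, home$centroid_lon)) else NA_real_,
      siglocsvisited = as.numeric(length(dwell_by_cl)),
      avgflightlen = if (nrow(fl)) mean(fl$length_m) else 0,
      stdflightlen = .sd_or_na(fl$length_m),
      avgflightdur = if (nrow(fl)) mean(fl$duration_min) else 0,
      stdflightdur = .sd_or_na(fl$duration_min),
      probpause = if (covered_min > 0)
        max(0, min(1, fp$pause_min / covered_min)) else NA_real_,
      siglocentropy = .shannon(as.numeric(dwell_by_cl)),
      minsmissing = max(0, seg_min - minute_bins),
      circdnrtn = .day_dwell_cosine(local_date, cluster, dwell),
      wkenddayrtn = {
        wk <- lubridate::wday(local_date, week_start = 1) >= 6
        s1 <- .day_dwell_cosine(local_date[wk], cluster[wk], dwell[wk])
        s2 <- .day_dwell_cosine(local_date[!wk], cluster[!wk], dwell[!wk])
        if (all(is.na(c(s1, s2)))) NA_real_ else mean(c(s1, s2), na.rm = TRUE)
      },
      minutesdataused = as.numeric(minute_bins))
  }, by = instance_id] else NULL
  out <- .emit_features(instances, stats, "locations", "barnett",
                        zero_fill = c("disttravelled", "siglocsvisited",
                                      "minutesdataused"))
  # a segment with no points at all is fully missing
  mm <- "barnett_locations_minsmissing"
  seg_min_all <- (out$seg_end_utc_ms - out$seg_start_utc_ms) / 60000
  v <- out[[mm]]
  v[is.na(v)] <- seg_min_all[is.na(v)]
  out[, (mm) := v]
  out[]
}
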