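# The five data-exploration plots, rendered as self-contained interactive
# HTML documents (inline SVG with hover tooltips; no external assets, so a
# report renders anywhere). Registry is fixed at exactly five plot ids.

.PLOT_IDS <- c("yield_histogram", "yield_heatmap_participant",
               "sensed_rows_heatmap", "yield_per_segment_heatmap",
               "feature_correlation_heatmap")

#' Registered quality-control plot identifiers
#' @return character vector of the five plot ids
#' @export
plot_registry <- function() .PLOT_IDS

.svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.html_doc <- function(title, body, path, warning_banner = NULL) {
  banner <- if (!is.null(warning_banner)) {
    sprintf("<div style='background:#ffdddd;padding:8px;border:1px solid #c00'>%s</div>",
            .svg_esc(warning_banner))
  } else ""
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'><title>",
    .svg_esc(title), "</title></head><body style='font-family:sans-serif'>",
    "<h2>", .svg_esc(title), "</h2>", banner, body, "</body></html>")
  writeLines(html, path)
  invisible(path)
}

# blue-red diverging or white-blue sequential fill
.fill_seq <- function(v, lo = 0, hi = 1) {
  t <- pmin(1, pmax(0, (v - lo) / max(hi - lo, 1e-12)))
  sprintf("rgb(%d,%d,255)", round(255 * (1 - t)), round(255 * (1 - t)))
}
.fill_div <- function(v) {
  t <- pmin(1, pmax(-1, v))
  ifelse(is.na(t), "rgb(220,220,220)",
         ifelse(t >= 0,
                sprintf("rgb(255,%d,%d)", round(255 * (1 - t)),
                        round(255 * (1 - t))),
                sprintf("rgb(%d,%d,255)", round(255 * (1 + t)),
                        round(255 * (1 + t)))))
}

.svg_heatmap <- function(mat, row_labels, col_labels, fills, tooltips,
                         cell = 18, pad_l = 160, pad_t = 90) {
  nr <- nrow(mat); nc <- ncol(mat)
  w <- pad_l + nc * cell + 20
  h <- pad_t + nr * cell + 20
  parts <- sprintf("<svg xmlns='http://www.w3.org/2000/svg' width='%d' height='%d'>",
                   w, h)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    parts <- c(parts, sprintf(
      "<rect x='%d' y='%d' width='%d' height='%d' fill='%s' stroke='#fff'><title>%s</title></rect>",
      pad_l + (j - 1) * cell, pad_t + (i - 1) * cell, cell, cell,
      fills[i, j], .svg_esc(tooltips[i, j])))
  }
  for (i in seq_len(nr)) {
    parts <- c(parts, sprintf(
      "<text x='%d' y='%d' font-size='10' text-anchor='end'>%s</text>",
      pad_l - 4, pad_t + i * cell - 5, .svg_esc(row_labels[i])))
  }
  for (j in seq_len(nc)) {
    parts <- c(parts, sprintf(
      "<text x='%d' y='%d' font-size='10' transform='rotate(-60 %d %d)'>%s</text>",
      pad_l + (j - 1) * cell + 9, pad_t - 6,
      pad_l + (j - 1) * cell + 9, pad_t - 6, .svg_esc(col_labels[j])))
  }
  paste(c(parts, "</svg>"), collapse = "\n")
}

#' Histogram of per-participant data yield
#'
#' Bins participants' ratiovalidyieldedminutes (averaged over segments) into
#' `bins` equal-width bins on [0, 1].
#' @param yield_dt data.table with pid and a yield ratio column
#' @param path output HTML path
#' @param ratio_col column to histogram
#' @param bins number of bins (default 20)
#' @export
plot_yield_histogram <- function(yield_dt, path,
                                 ratio_col = "rapids_data_yield_ratiovalidyieldedminutes",
                                 bins = 20) {
  if (is.null(yield_dt) || !nrow(yield_dt)) {
    return(.html_doc("Data yield histogram", "", path,
                     "No yield data available"))
  }
  per_pid <- yield_dt[, .(ratio = mean(get(ratio_col), na.rm = TRUE)),
                      by = pid]
  br <- seq(0, 1, length.out = bins + 1)
  cnt <- graphics::hist(pmin(pmax(per_pid$ratio, 0), 1), breaks = br,
                        plot = FALSE)$counts
  maxc <- max(cnt, 1)
  bar_w <- 24
  parts <- sprintf("<svg xmlns='http://www.w3.org/2000/svg' width='%d' height='260'>",
                   40 + bins * bar_w)
  for (k in seq_len(bins)) {
    hpx <- round(200 * cnt[k] / maxc)
    parts <- c(parts, sprintf(
      "<rect x='%d' y='%d' width='%d' height='%d' fill='steelblue'><title>[%.2f, %.2f): %d participant(s)</title></rect>",
      20 + (k - 1) * bar_w, 220 - hpx, bar_w - 2, hpx, br[k], br[k + 1], cnt[k]))
    if (k %% 5 == 1) {
      parts <- c(parts, sprintf(
        "<text x='%d' y='238' font-size='10'>%.2f</text>",
        20 + (k - 1) * bar_w, br[k]))
    }
  }
  .html_doc("Data yield histogram", paste(c(parts, "</svg>"), collapse = "\n"),
            path)
}

#' Heatmap of data yield per participant and segment date
#' @param yield_dt yield FeatureRow table (pid, instance_id, ratio column)
#' @param path output HTML path
#' @param ratio_col yield ratio column
#' @export
plot_yield_heatmap_participant <- function(yield_dt, path,
                                           ratio_col = "rapids_data_yield_ratiovalidyieldedminutes") {
  if (is.null(yield_dt) || !nrow(yield_dt)) {
    return(.html_doc("Data yield per participant", "", path,
                     "No yield data available"))
  }
  d <- yield_dt[, .(pid, key = instance_id, v = get(ratio_col))]
  wide <- data.table::dcast(d, pid ~ key, value.var = "v")
  m <- as.matrix(wide[, -1])
  fills <- matrix(.fill_seq(as.vector(m)), nrow(m))
  tips <- matrix(sprintf("%s / %s: %.3f",
                         rep(wide$pid, ncol(m)),
                         rep(colnames(m), each = nrow(m)),
                         as.vector(m)), nrow(m))
  .html_doc("Data yield per participant",
            .svg_heatmap(m, wide$pid, colnames(m), fills, tips), path)
}

#' Heatmap of sensed row counts per participant and sensor
#' @param counts_dt data.table (pid, sensor, n_rows)
#' @param path output HTML path
#' @export
plot_sensed_rows_heatmap <- function(counts_dt, path) {
  if (is.null(counts_dt) || !nrow(counts_dt)) {
    return(.html_doc("Sensed rows per sensor", "", path,
                     "No raw data available"))
  }
  wide <- data.table::dcast(counts_dt, pid ~ sensor, value.var = "n_rows",
                            fill = 0)
  m <- as.matrix(wide[, -1])
  lm <- log10(m + 1)
  fills <- matrix(.fill_seq(as.vector(lm), 0, max(lm, 1)), nrow(m))
  tips <- matrix(sprintf("%s / %s: %d rows",
                         rep(wide$pid, ncol(m)),
                         rep(colnames(m), each = nrow(m)),
                         as.vector(m)), nrow(m))
  .html_doc("Sensed rows per sensor",
            .svg_heatmap(m, wide$pid, colnames(m), fills, tips), path)
}

#' Heatmap of data yield per segment label
#' @param yield_dt yield FeatureRow table
#' @param path output HTML path
#' @param ratio_col yield ratio column
#' @export
plot_yield_per_segment_heatmap <- function(yield_dt, path,
                                           ratio_col = "rapids_data_yield_ratiovalidyieldedminutes") {
  if (is.null(yield_dt) || !nrow(yield_dt)) {
    return(.html_doc("Data yield per segment", "", path,
                     "No yield data available"))
  }
  d <- yield_dt[, .(v = mean(get(ratio_col), na.rm = TRUE)),
                by = .(pid, label)]
  wide <- data.table::dcast(d, pid ~ label, value.var = "v")
  m <- as.matrix(wide[, -1])
  fills <- matrix(.fill_seq(as.vector(m)), nrow(m))
  tips <- matrix(sprintf("%s / %s: %.3f",
                         rep(wide$pid, ncol(m)),
                         rep(colnames(m), each = nrow(m)),
                         as.vector(m)), nrow(m))
  .html_doc("Data yield per segment",
            .svg_heatmap(m, wide$pid, colnames(m), fills, tips), path)
}

#' Pairwise feature-correlation matrix
#'
#' Pearson (default) or Spearman correlation over pairwise-complete
#' observations; pairs with fewer than `min_overlap` complete rows are NA.
#' @param features merged feature matrix (numeric feature columns)
#' @param min_overlap minimum complete pairs (default 30)
#' @param method "pearson" or "spearman"
#' @return correlation matrix
#' @export
feature_correlations <- function(features, min_overlap = 30,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  num <- features[, vapply(features, is.numeric, TRUE), with = FALSE]
  drop <- c("seg_start_utc_ms", "seg_end_utc_ms")
  num <- num[, setdiff(names(num), drop), with = FALSE]
  m <- as.matrix(num)
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                    method = method))
  nobs <- crossprod(!is.na(m))
  cc[nobs < min_overlap] <- NA_real_
  cc
}

#' Feature correlation heatmap
#' @param features merged feature matrix
#' @param path output HTML path
#' @param min_overlap minimum complete pairs per correlation
#' @param method correlation estimator
#' @export
plot_feature_correlation_heatmap <- function(features, path,
                                             min_overlap = 30,
                                             method = "pearson") {
  if (is.null(features) || !nrow(features)) {
    return(.html_doc("Feature correlations", "", path,
                     "Empty feature matrix"))
  }
  cc <- feature_correlations(features, min_overlap, method)
  if (!length(cc)) {
    return(.html_doc("Feature correlations", "", path,
                     "No numeric features to correlate"))
  }
  fills <- matrix(.fill_div(as.vector(cc)), nrow(cc))
  tips <- matrix(sprintf("%s ~ %s: %.3f",
                         rep(rownames(cc), ncol(cc)),
                         rep(colnames(cc), each = nrow(cc)),
                         as.vector(cc)), nrow(cc))
  .html_doc("Feature correlations",
            .svg_heatmap(cc, rownames(cc), colnames(cc), fills, tips,
                         cell = 14, pad_l = 260, pad_t = 200), path)
}
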