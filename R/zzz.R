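#' @importFrom data.table := .N .SD data.table as.data.table setDT setorder
#'   setnames rbindlist fwrite fread copy setkey foverlaps setattr
#' @importFrom stats var sd median complete.cases cor rnorm runif rpois setNames
#' @importFrom utils head tail
NULL

# R finds the IANA database through TZDIR or a small set of hard-coded paths.
# In minimal containers /usr/share/zoneinfo may be absent while a conda R
# ships its own copy next to R.home(); without this probe every tz conversion
# silently degenerates to UTC, which breaks all local-time math.
.fix_tzdir <- function() {
  probe <- function(dir) {
    nzchar(dir) && file.exists(file.path(dir, "America", "New_York"))
  }
  if (probe(Sys.getenv("TZDIR"))) return(invisible(TRUE))
  candidates <- c(
    file.path(R.home("share"), "zoneinfo"),
    normalizePath(file.path(R.home(), "..", "..", "share", "zoneinfo"),
                  mustWork = FALSE),
    "/usr/share/zoneinfo",
    "/opt/conda/share/zoneinfo"
  )
  for (d in candidates) {
    if (probe(d)) {
      Sys.setenv(TZDIR = d)
      return(invisible(TRUE))
    }
  }
  warning("No IANA zoneinfo database found; non-UTC conversions may be wrong")
  invisible(FALSE)
}

.onLoad <- function(libname, pkgname) {
  .fix_tzdir()
}

# ---- small shared helpers ----

#' Sample standard deviation, NA below two observations
#' @param x numeric vector
#' @return sample sd or NA_real_
#' @keywords internal
.sd_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

#' Statistical mode with deterministic tie-break (smallest value)
#' @keywords internal
.mode_min <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  if (is.numeric(x)) min(as.numeric(winners)) else sort(winners)[1L]
}

#' Shannon entropy (natural log) of a probability weight vector
#'
#' Weights are normalized internally; zero weights contribute nothing.
#' Returns 0 for a single observation or an all-zero weight vector.
#' @keywords internal
.shannon <- function(w) {
  w <- w[!is.na(w) & w > 0]
  if (length(w) <= 1L) return(0)
  p <- w / sum(w)
  -sum(p * log(p))
}

#' Minutes elapsed since local midnight for a POSIXct vector
#' @keywords internal
.minutes_since_midnight <- function(dt) {
  as.numeric(dt - lubridate::floor_date(dt, "day"), units = "mins")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
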