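#' Read a per-minute weather series
#'
#' Loads the station's weather CSV: ISO-8601 `timestamp` plus `wind_speed`
#' (m/s), `wind_direction` (deg), `temperature` (degC), `precipitation`
#' (mm/h) and `relative_humidity` (%), recorded at a 1-minute cadence.
#' Timestamps must be strictly increasing; wind and precipitation must be
#' non-negative.
#'
#' @param path CSV path, or a data frame already in that shape.
#' @return object of class `weather_series` (a validated data frame).
#' @export
read_weather <- function(path) {
  w <- if (is.character(path)) utils::read.csv(path) else as.data.frame(path)
  required <- c("timestamp", "wind_speed", "precipitation")
  missing <- setdiff(required, names(w))
  if (length(missing) > 0L) {
    stop("weather series missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!inherits(w$timestamp, "POSIXct")) {
    w$timestamp <- as.POSIXct(as.character(w$timestamp), tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                             "%Y-%m-%dT%H:%M:%OS",
                                             "%Y-%m-%d %H:%M:%OS",
                                             "%Y-%m-%d %H:%M",
                                             "%Y-%m-%d"))
  }
  if (any(is.na(w$timestamp))) stop("unparseable timestamps", call. = FALSE)
  if (is.unsorted(w$timestamp, strictly = TRUE)) {
    stop("weather timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(w$wind_speed < 0) || any(w$precipitation < 0)) {
    stop("wind speed and precipitation must be >= 0", call. = FALSE)
  }
  class(w) <- c("weather_series", "data.frame")
  w
}

#' Weather statistics over one scan window
#'
#' Summarizes the 1-minute weather records over a scan acquisition window
#' `[scan_start, scan_start + duration]` (the station's scans take 21 min):
#' maximum and mean wind speed and total precipitation. Records at the window
#' edges are obtained by linear interpolation so windows not aligned to the
#' minute grid are handled exactly; precipitation intensity (mm/h) is
#' integrated trapezoidally into a depth (mm).
#'
#' @param weather a [read_weather()] series covering the window.
#' @param scan_start window start (`POSIXct` or parseable string).
#' @param duration window length in minutes (default 21).
#' @return list with `scan_start`, `duration`, `wind_max`, `wind_mean`,
#'   `precip_total_mm`, `precip_max`.
#' @export
window_stats <- function(weather, scan_start, duration = 21) {
  stopifnot(inherits(weather, "weather_series"))
  if (!inherits(scan_start, "POSIXct")) {
    scan_start <- as.POSIXct(scan_start, tz = "UTC")
  }
  t0 <- as.numeric(scan_start)
  t1 <- t0 + duration * 60
  tt <- as.numeric(weather$timestamp)
  if (t0 < tt[1] || t1 > tt[length(tt)]) {
    stop("scan window not covered by weather series", call. = FALSE)
  }
  # slice the covering index range once; interpolate only at the edges
  i0 <- findInterval(t0, tt)
  i1 <- findInterval(t1, tt)
  sel <- max(1L, i0):min(length(tt), i1 + 1L)
  ts <- tt[sel]
  at <- function(col, t) stats::approx(ts, weather[[col]][sel], xout = t)$y
  tw <- unique(c(t0, ts[ts >= t0 & ts <= t1], t1))
  wind <- at("wind_speed", tw)
  precip <- at("precipitation", tw)
  list(scan_start = scan_start,
       duration = duration,
       wind_max = max(wind),
       wind_mean = mean(wind),
       wind_start = wind[1],
       precip_total_mm = sum(diff(tw) / 3600 * (utils::head(precip, -1) +
                                                  utils::tail(precip, -1)) / 2),
       precip_max = max(precip))
}

#' Gate scans on calm-weather conditions
#'
#' Applies the long-term-analysis selection criterion to a set of scans: a
#' scan passes iff its window wind statistic is strictly below `wind_limit`
#' (3 m/s, calm to light breeze on the Beaufort scale) and its total
#' precipitation equals `precip_limit` (0 mm, to within 1e-9). The wind
#' statistic defaults to the window maximum — a 21-minute scan is corrupted
#' by any gust — with `"mean"` and `"start"` (instantaneous at scan start)
#' available.
#'
#' @param weather a [read_weather()] series.
#' @param scan_times vector of scan start times (`POSIXct`).
#' @param duration scan duration in minutes.
#' @param wind_limit strict upper wind bound in m/s (default 3).
#' @param precip_limit required precipitation total in mm (default 0).
#' @param stat wind statistic: `"max"`, `"mean"` or `"start"`.
#' @return data frame of class `scan_quality_flags`: one row per scan with
#'   window statistics and logical `passed`.
#' @export
gate_scans <- function(weather, scan_times, duration = 21, wind_limit = 3,
                       precip_limit = 0, stat = c("max", "mean", "start")) {
  stat <- match.arg(stat)
  if (!inherits(scan_times, "POSIXct")) {
    scan_times <- as.POSIXct(scan_times, tz = "UTC")
  }
  rows <- lapply(scan_times, function(ts) {
    s <- window_stats(weather, ts, duration)
    data.frame(scan_time = ts, wind_max = s$wind_max,
               wind_mean = s$wind_mean, wind_start = s$wind_start,
               precip_total_mm = s$precip_total_mm)
  })
  flags <- do.call(rbind, rows)
  wind_stat <- switch(stat, max = flags$wind_max, mean = flags$wind_mean,
                      start = flags$wind_start)
  flags$passed <- wind_stat < wind_limit &
    abs(flags$precip_total_mm - precip_limit) <= 1e-9
  attr(flags, "criterion") <- list(wind_limit = wind_limit,
                                   precip_limit = precip_limit,
                                   stat = stat, duration = duration)
  class(flags) <- c("scan_quality_flags", "data.frame")
  flags
}

#' Monthly summary of gated scans
#'
#' Partitions quality flags by calendar month and reports scan counts,
#' passing counts and pass rates.
#'
#' @param flags a [gate_scans()] result.
#' @param digits decimals for the pass-rate percentage (default 1).
#' @return data frame with columns `month`, `scans`, `passed`, `pass_rate`
#'   (percent).
#' @export
monthly_summary <- function(flags, digits = 1) {
  stopifnot(inherits(flags, "scan_quality_flags"), nrow(flags) > 0L)
  month <- format(flags$scan_time, "%Y-%m")
  agg <- stats::aggregate(flags$passed, by = list(month = month),
                          FUN = function(v) c(n = length(v), p = sum(v)))
  out <- data.frame(month = agg$month,
                    scans = as.integer(agg$x[, "n"]),
                    passed = as.integer(agg$x[, "p"]))
  out$pass_rate <- round(out$passed / out$scans * 100, digits)
  out[order(out$month), , drop = FALSE]
}
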