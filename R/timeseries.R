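# Water-level series container and logger CSV I/O.

#' Water-level time series
#'
#' Container for a uniformly sampled water-level record from a pressure
#' logger ("diver"). Timestamps must be strictly increasing on a nominal
#' grid (default 5 minutes); departures from the grid are recorded as gaps,
#' never filled. Levels are in centimetres in a declared datum:
#'
#' * `"raw_pressure"` — uncompensated absolute pressure, cm H2O equivalent;
#' * `"open_water_local"` — water level after barometric compensation, in
#'   the local datum of the logger (zero is arbitrary);
#' * `"surface_relative"` — water level relative to the soil surface, so
#'   the surface sits at exactly 0 cm and positive values mean inundation.
#'
#' Timestamps are stored timezone-naive (internally UTC); mixing clock
#' conventions between series that are combined is the caller's
#' responsibility.
#'
#' @param time `POSIXct` vector, strictly increasing.
#' @param level_cm numeric vector of levels in cm, finite.
#' @param datum one of `"raw_pressure"`, `"open_water_local"`,
#'   `"surface_relative"`.
#' @param site_id optional site identifier.
#' @param dt_min nominal sampling interval in minutes.
#' @return An object of class `water_level_series`: a list with elements
#'   `time`, `level_cm`, `datum`, `site_id`, `dt_min` and `gaps` (a
#'   data frame of intervals where samples are missing from the grid).
#' @seealso [read_series()], [compensate_barometric()], [extract_events()]
#' @export
water_level_series <- function(time, level_cm, datum = "open_water_local",
                               site_id = NA_character_, dt_min = 5) {
  datum <- match.arg(datum, c("raw_pressure", "open_water_local", "surface_relative"))
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct")
  if (length(time) != length(level_cm)) stop("time and level lengths differ")
  if (length(time) == 0L) stop("empty series")
  if (anyNA(time)) stop("missing timestamps")
  dts <- diff(as.numeric(time)) / 60
  if (any(dts <= 0)) {
    stop("timestamps must be strictly increasing (duplicated or out-of-order timestamp at position ",
         which(dts <= 0)[1] + 1L, ")")
  }
  if (!all(is.finite(level_cm))) stop("levels must be finite")
  gap <- which(dts > dt_min + 0.5)
  gaps <- data.frame(
    from = time[gap], to = time[gap + 1L],
    missing_min = dts[gap] - dt_min
  )
  structure(
    list(time = time, level_cm = as.numeric(level_cm), datum = datum,
         site_id = site_id, dt_min = dt_min, gaps = gaps),
    class = "water_level_series"
  )
}

#' @export
print.water_level_series <- function(x, ...) {
  cat("<water_level_series> site:", x$site_id, " datum:", x$datum, "\n")
  cat("  ", length(x$time), " samples @ ", x$dt_min, " min, ",
      format(x$time[1]), " .. ", format(x$time[length(x$time)]), "\n", sep = "")
  cat("  level range [cm]: ", paste(round(range(x$level_cm), 1), collapse = " .. "),
      "; gaps: ", nrow(x$gaps), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.water_level_series <- function(x, ...) {
  data.frame(timestamp = x$time, level_cm = x$level_cm)
}

#' @export
length.water_level_series <- function(x) length(x$time)

#' @export
plot.water_level_series <- function(x, ..., ylab = "water level [cm]") {
  plot(x$time, x$level_cm, type = "l", xlab = "", ylab = ylab, ...)
  if (x$datum == "surface_relative") graphics::abline(h = 0, lty = 2)
  invisible(x)
}

# Parse ISO 8601-ish timestamps ("T" or space separator); error on failure.
parse_timestamps <- function(x) {
  x <- trimws(as.character(x))
  fmt <- if (any(grepl("T", x, fixed = TRUE))) "%Y-%m-%dT%H:%M:%S" else "%Y-%m-%d %H:%M:%S"
  out <- as.POSIXct(x, tz = "UTC", format = fmt)
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("malformed timestamp at row ", bad[1], ": '", x[bad[1]], "'")
  }
  out
}

# 1 cm H2O column corresponds to 0.980665 hPa.
HPA_PER_CM_H2O <- 0.980665

#' Read a water-level logger CSV
#'
#' Expects a header and either a `level_cm` column or, for the pressure
#' dialect, a `pressure_hpa` column (converted at 1 cm H2O = 0.980665 hPa).
#' The first column must be `timestamp` (ISO 8601, `T` or space separated).
#' Missing 5-minute steps are recorded as gaps; duplicated or out-of-order
#' timestamps are an error.
#'
#' @param path CSV file path.
#' @param datum declared datum of the series (see [water_level_series()]);
#'   defaults to `"raw_pressure"` for the pressure dialect and
#'   `"open_water_local"` otherwise.
#' @param site_id optional site identifier (defaults to the file name).
#' @param dt_min nominal sampling interval in minutes.
#' @return A [water_level_series()].
#' @export
read_series <- function(path, datum = NULL, site_id = NULL, dt_min = 5) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(df)) stop("missing 'timestamp' column in ", path)
  tt <- parse_timestamps(df$timestamp)
  if ("level_cm" %in% names(df)) {
    lev <- as.numeric(df$level_cm)
    if (is.null(datum)) datum <- "open_water_local"
  } else if ("pressure_hpa" %in% names(df)) {
    lev <- as.numeric(df$pressure_hpa) / HPA_PER_CM_H2O
    if (is.null(datum)) datum <- "raw_pressure"
  } else {
    stop("need a 'level_cm' or 'pressure_hpa' column in ", path)
  }
  if (is.null(site_id)) site_id <- sub("\\.csv$", "", basename(path))
  water_level_series(tt, lev, datum = datum, site_id = site_id, dt_min = dt_min)
}

#' Write a water-level series to CSV
#'
#' Writes `timestamp,level_cm` with ISO 8601 timestamps and 17 significant
#' digits so that a read/write round trip preserves timestamps exactly and
#' levels to well below measurement resolution.
#'
#' @param series a [water_level_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "water_level_series"))
  df <- data.frame(
    timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    level_cm = formatC(series$level_cm, format = "g", digits = 17)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Barometric compensation of a raw pressure series
#'
#' Subtracts atmospheric pressure (measured by a logger in air) from a raw
#' absolute-pressure series, both in cm H2O equivalent. The atmospheric
#' series is linearly interpolated to the raw series' timestamps; gaps in
#' the atmospheric record larger than `max_gap_min` inside the raw window
#' are a coverage error rather than silently bridged.
#'
#' @param raw raw absolute-pressure [water_level_series()] (cm H2O).
#' @param baro atmospheric-pressure series covering `raw`'s window.
#' @param max_gap_min largest atmospheric gap (minutes) interpolation may
#'   bridge.
#' @return A [water_level_series()] with datum `"open_water_local"`.
#' @export
compensate_barometric <- function(raw, baro, max_gap_min = 360) {
  stopifnot(inherits(raw, "water_level_series"), inherits(baro, "water_level_series"))
  r0 <- raw$time[1]; r1 <- raw$time[length(raw$time)]
  if (baro$time[1] > r0 || baro$time[length(baro$time)] < r1) {
    stop("atmospheric series does not cover the raw series' window (coverage error)")
  }
  if (nrow(baro$gaps)) {
    over <- baro$gaps$to > r0 & baro$gaps$from < r1 & baro$gaps$missing_min > max_gap_min
    if (any(over)) {
      stop("atmospheric gap of ", round(max(baro$gaps$missing_min[over])),
           " min exceeds max_gap_min = ", max_gap_min, " (coverage error)")
    }
  }
  b <- stats::approx(as.numeric(baro$time), baro$level_cm,
                     xout = as.numeric(raw$time))$y
  water_level_series(raw$time, raw$level_cm - b, datum = "open_water_local",
                     site_id = raw$site_id, dt_min = raw$dt_min)
}

#' Check a measurement window against the lunar tidal cycle
#'
#' A spring--neap (lunar) cycle is about 30 days; inundation statistics are
#' most representative when the record spans 30 days or a multiple thereof.
#' Shorter or longer windows are usable but yield a warning, not an error.
#'
#' @param series a [water_level_series()].
#' @param multiple_days target cycle length in days (default 30).
#' @param tol_days allowed deviation from the nearest positive multiple.
#' @return A list of class `window_report` with the span in days, counts of
#'   observed/expected samples, completeness, the deviation from the
#'   nearest multiple and a `conforming` flag.
#' @export
validate_window <- function(series, multiple_days = 30, tol_days = 1) {
  stopifnot(inherits(series, "water_level_series"))
  n <- length(series$time)
  if (n == 0L) stop("empty series")
  span_min <- as.numeric(difftime(series$time[n], series$time[1], units = "mins")) +
    series$dt_min
  span_days <- span_min / 1440
  n_expected <- round(span_min / series$dt_min)
  mult <- max(1, round(span_days / multiple_days))
  deviation <- span_days - mult * multiple_days
  conforming <- abs(deviation) <= tol_days
  rep <- structure(
    list(span_days = span_days, n_obs = n, n_expected = n_expected,
         completeness = n / n_expected, n_gaps = nrow(series$gaps),
         nearest_multiple_days = mult * multiple_days,
         deviation_days = deviation, conforming = conforming),
    class = "window_report"
  )
  if (!conforming) {
    warning(sprintf(
      "window spans %.1f days: not within %g days of a multiple of %g days",
      span_days, tol_days, multiple_days))
  }
  rep
}

#' @export
print.window_report <- function(x, ...) {
  cat(sprintf("<window_report> span %.2f d, %d/%d samples (%.1f%% complete), %d gap(s)\n",
              x$span_days, x$n_obs, x$n_expected, 100 * x$completeness, x$n_gaps))
  cat(sprintf("  nearest multiple: %g d (deviation %+.2f d) -> %s\n",
              x$nearest_multiple_days, x$deviation_days,
              if (x$conforming) "conforming" else "NOT conforming"))
  invisible(x)
}

# Observed (gap-adjusted) span in days: samples actually present x dt.
observed_span_days <- function(series) {
  length(series$time) * series$dt_min / 1440
}
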