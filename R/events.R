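# Inundation-event extraction and hydroperiod statistics.

#' Extract inundation events from a surface-relative series
#'
#' A sample is wet when its level is strictly above the soil surface
#' (0 cm). Two cleaning rules with a common minimum duration (default 15
#' minutes) remove logger noise and micro-fluctuations:
#'
#' 1. dry spells shorter than the minimum that are flanked by wet samples
#'    are merged into the surrounding inundation;
#' 2. wet runs still shorter than the minimum are discarded.
#'
#' Rules are applied in that order. Durations are counted on the sampling
#' grid as (number of samples) x `dt_min`; no sub-sample interpolation is
#' attempted. Runs never merge across recorded data gaps.
#'
#' @param series a [water_level_series()] with datum `"surface_relative"`.
#' @param min_duration_min minimum duration (minutes) of both inundation
#'   and dry-fall.
#' @return A data frame with one row per event: `start`, `end` (end is the
#'   start of the last wet sample plus one interval), `duration_min`,
#'   `peak_level_cm`, `n_samples`.
#' @export
extract_events <- function(series, min_duration_min = 15) {
  stopifnot(inherits(series, "water_level_series"))
  if (series$datum != "surface_relative") {
    stop("datum error: extract_events needs a surface_relative series, got '",
         series$datum, "'")
  }
  dt <- series$dt_min
  min_n <- ceiling(min_duration_min / dt)
  # split at data gaps so runs never bridge missing time
  dts <- diff(as.numeric(series$time)) / 60
  chunk <- cumsum(c(0, dts > dt + 0.5))
  out <- list()
  for (ch in split(seq_along(series$time), chunk)) {
    wet <- series$level_cm[ch] > 0
    wet <- fill_short_runs(wet, FALSE, min_n)   # merge short dry-falls
    wet <- fill_short_runs(wet, TRUE, min_n)    # then drop short wet runs
    if (!any(wet)) next
    r <- rle(wet)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- ch[starts[j]:ends[j]]
      out[[length(out) + 1L]] <- data.frame(
        start = series$time[idx[1]],
        end = series$time[idx[length(idx)]] + dt * 60,
        duration_min = length(idx) * dt,
        peak_level_cm = max(series$level_cm[idx]),
        n_samples = length(idx)
      )
    }
  }
  if (!length(out)) {
    return(data.frame(start = series$time[0], end = series$time[0],
                      duration_min = numeric(0), peak_level_cm = numeric(0),
                      n_samples = integer(0)))
  }
  ev <- do.call(rbind, out)
  ev[order(ev$start), , drop = FALSE]
}

# Flip runs of `value` shorter than min_n samples. Runs touching the chunk
# boundary are only flipped when dropping wet runs (value TRUE): a short dry
# spell at a boundary is not evidence of a merged inundation.
fill_short_runs <- function(x, value, min_n) {
  r <- rle(x)
  k <- length(r$lengths)
  for (j in seq_len(k)) {
    if (r$values[j] == value && r$lengths[j] < min_n) {
      interior <- j > 1L && j < k
      if (value || interior) r$values[j] <- !value
    }
  }
  inverse.rle(r)
}

#' Summarise inundation events into hydroperiod statistics
#'
#' Computes the two duration-of-inundation variables used for
#' classification plus a flooding frequency:
#'
#' * `min_per_day` — total inundated minutes divided by the span in days;
#' * `min_per_inundation` — total inundated minutes divided by the number
#'   of events (0 with a `no_events` flag when there are none);
#' * `freq_per_30d` — events per 30 days.
#'
#' The span is gap-adjusted: it counts observed samples only, so missing
#' intervals inflate neither numerator nor denominator.
#'
#' @param events event table from [extract_events()].
#' @param series the series the events came from (used for the gap-adjusted
#'   span), or `NULL` if `span_days` is given directly.
#' @param span_days explicit span in days (overrides `series`).
#' @return A list of class `inundation_summary`.
#' @export
summarize_inundation <- function(events, series = NULL, span_days = NULL) {
  if (is.null(span_days)) {
    if (is.null(series)) stop("need `series` or `span_days`")
    span_days <- observed_span_days(series)
  }
  if (span_days <= 0) stop("span must be positive")
  total <- sum(events$duration_min)
  n <- nrow(events)
  structure(
    list(
      events = events,
      n_events = n,
      total_min = total,
      min_per_day = total / span_days,
      min_per_inundation = if (n > 0) total / n else 0,
      freq_per_30d = n * 30 / span_days,
      span_days = span_days,
      no_events = n == 0L
    ),
    class = "inundation_summary"
  )
}

#' @export
print.inundation_summary <- function(x, ...) {
  cat(sprintf("<inundation_summary> %d event(s) over %.2f d%s\n", x$n_events,
              x$span_days, if (x$no_events) " [no events]" else ""))
  cat(sprintf("  min/day: %.1f   min/inundation: %.1f   freq/30d: %.1f\n",
              x$min_per_day, x$min_per_inundation, x$freq_per_30d))
  invisible(x)
}

#' Write an event table to CSV
#'
#' @param events event table from [extract_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(
    start = format(events$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    end = format(events$end, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    duration_min = events$duration_min,
    peak_level_cm = events$peak_level_cm
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
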