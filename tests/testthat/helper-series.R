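# Test helpers: quick series construction and an independent event oracle.

t0 <- as.POSIXct("2011-12-20 00:00:00", tz = "UTC")

# Build a series from a level vector on the 5-minute grid.
make_wls <- function(level, datum = "surface_relative", start = t0, dt_min = 5,
                     site_id = "test") {
  time <- start + (seq_along(level) - 1) * dt_min * 60
  water_level_series(time, level, datum = datum, site_id = site_id,
                     dt_min = dt_min)
}

# Independent brute-force event scanner: sample-by-sample passes applying
# (1) interior short-dry-run filling, (2) short-wet-run dropping. Returns a
# list of c(first_index, last_index) per event. Deliberately written as
# explicit while-loops, unlike the run-length-encoding implementation.
oracle_events <- function(wet, dt_min = 5, min_min = 15) {
  n <- length(wet)
  min_n <- ceiling(min_min / dt_min)
  w <- wet
  i <- 1L
  while (i <= n) {
    if (!w[i]) {
      j <- i
      while (j < n && !w[j + 1L]) j <- j + 1L
      if (i > 1L && j < n && (j - i + 1L) < min_n) w[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  ev <- list()
  i <- 1L
  while (i <= n) {
    if (w[i]) {
      j <- i
      while (j < n && w[j + 1L]) j <- j + 1L
      if ((j - i + 1L) >= min_n) ev[[length(ev) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  ev
}

# Short default scenario for simulator-based tests.
test_scenario <- function(span_days = 30) tide_scenario(span_days = span_days)
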