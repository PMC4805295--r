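test_that("CSV parsing detects gaps and rejects disorder", {
  d <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,level_cm",
               "2011-12-20T00:00:00,10",
               "2011-12-20T00:05:00,11.5",
               "2011-12-20T00:10:00,12"), d)
  s <- read_series(d)
  expect_s3_class(s, "water_level_series")
  expect_length(s, 3)
  expect_equal(nrow(s$gaps), 0)
  expect_equal(s$level_cm, c(10, 11.5, 12))

  # one missing 5-min step -> one recorded 5-min gap
  writeLines(c("timestamp,level_cm",
               "2011-12-20T00:00:00,10",
               "2011-12-20T00:05:00,11",
               "2011-12-20T00:15:00,12"), d)
  s <- read_series(d)
  expect_equal(nrow(s$gaps), 1)
  expect_equal(s$gaps$missing_min, 5)

  # duplicated timestamp -> order error
  writeLines(c("timestamp,level_cm",
               "2011-12-20T00:00:00,10",
               "2011-12-20T00:00:00,11"), d)
  expect_error(read_series(d), "increasing")

  # malformed timestamp -> parse error
  writeLines(c("timestamp,level_cm",
               "2011-12-20T00:00:00,10",
               "not-a-time,11"), d)
  expect_error(read_series(d), "malformed")
})

test_that("pressure dialect converts hPa to cm H2O", {
  d <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,pressure_hpa",
               "2011-12-20T00:00:00,980.665",
               "2011-12-20T00:05:00,1961.33"), d)
  s <- read_series(d)
  expect_equal(s$datum, "raw_pressure")
  expect_equal(s$level_cm, c(1000, 2000))
})

test_that("write/read round trip preserves timestamps and levels", {
  set.seed(42)
  s <- make_wls(cumsum(rnorm(200)) + 0.123456789, datum = "open_water_local")
  f <- tempfile(fileext = ".csv")
  write_series(s, f)
  s2 <- read_series(f, datum = "open_water_local")
  expect_identical(s2$time, s$time)
  expect_lt(max(abs(s2$level_cm - s$level_cm)), 1e-9)
})

test_that("barometric compensation subtracts interpolated pressure", {
  set.seed(7)
  raw <- make_wls(1030 + cumsum(rnorm(288)), datum = "raw_pressure")
  # identity: raw == baro -> all zero
  z <- compensate_barometric(raw, raw)
  expect_equal(z$level_cm, rep(0, 288))
  expect_equal(z$datum, "open_water_local")
  # constant offset
  baro <- make_wls(raw$level_cm - 10, datum = "raw_pressure")
  expect_equal(compensate_barometric(raw, baro)$level_cm, rep(10, 288))
})

test_that("hourly atmospheric record matches pointwise interpolation oracle", {
  set.seed(8)
  n <- 288
  raw <- make_wls(1030 + cumsum(rnorm(n)), datum = "raw_pressure")
  bt <- t0 + seq(0, n * 300, by = 3600)
  bl <- 1010 + cumsum(rnorm(length(bt), 0, 2))
  baro <- water_level_series(bt, bl, datum = "raw_pressure", dt_min = 60)
  out <- compensate_barometric(raw, baro)
  # brute-force pointwise linear interpolation
  oracle <- vapply(seq_len(n), function(i) {
    tx <- as.numeric(raw$time[i])
    j <- max(which(as.numeric(bt) <= tx))
    if (as.numeric(bt[j]) == tx) bv <- bl[j]
    else {
      f <- (tx - as.numeric(bt[j])) / (as.numeric(bt[j + 1]) - as.numeric(bt[j]))
      bv <- bl[j] * (1 - f) + bl[j + 1] * f
    }
    raw$level_cm[i] - bv
  }, numeric(1))
  expect_equal(out$level_cm, oracle, tolerance = 1e-12)
})

test_that("compensation is linear in the raw series", {
  set.seed(9)
  raw <- make_wls(1030 + cumsum(rnorm(100)), datum = "raw_pressure")
  baro <- make_wls(1015 + cumsum(rnorm(100, 0, 0.2)), datum = "raw_pressure")
  a <- compensate_barometric(raw, baro)
  shifted <- make_wls(raw$level_cm + 7.5, datum = "raw_pressure")
  b <- compensate_barometric(shifted, baro)
  expect_equal(b$level_cm, a$level_cm + 7.5)
})

test_that("compensation refuses inadequate atmospheric coverage", {
  raw <- make_wls(rep(1030, 100), datum = "raw_pressure")
  short <- make_wls(rep(1010, 50), datum = "raw_pressure")
  expect_error(compensate_barometric(raw, short), "coverage")
  # gap beyond the limit inside the window
  bt <- c(t0 + (0:10) * 300, t0 + (90:99) * 300)
  gappy <- water_level_series(bt, rep(1010, length(bt)), datum = "raw_pressure")
  expect_error(compensate_barometric(raw, gappy, max_gap_min = 60), "coverage")
})

test_that("window validation flags departures from the 30-day cycle", {
  ok <- make_wls(rep(1, 30 * 288), datum = "open_water_local")
  r <- validate_window(ok)
  expect_true(r$conforming)
  expect_equal(r$span_days, 30)
  expect_equal(r$completeness, 1)

  # 50 days: a valid record, but not a multiple of the lunar cycle
  long <- make_wls(rep(1, 50 * 288), datum = "open_water_local")
  expect_warning(r <- validate_window(long), "multiple")
  expect_false(r$conforming)

  # 28-day window: warning only, still usable
  short <- make_wls(rep(1, 28 * 288), datum = "open_water_local")
  expect_warning(r <- validate_window(short), "multiple")
  expect_false(r$conforming)
  expect_equal(r$span_days, 28)
})
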