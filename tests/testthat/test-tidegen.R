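test_that("harmonic synthesis matches the closed form and is deterministic", {
  sc <- tide_scenario(constituents = data.frame(
    name = "M2", amplitude_cm = 100, period_h = 12.42, phase_rad = 0),
    msl_offset_cm = 120, span_days = 2)
  ow <- generate_open_water(sc)
  th <- (seq_along(ow$time) - 1) / 12
  expect_equal(ow$level_cm, 120 + 100 * sin(2 * pi * th / 12.42),
               tolerance = 1e-12)
  expect_identical(generate_open_water(sc)$level_cm, ow$level_cm)
  expect_error(generate_open_water(
    tide_scenario(constituents = data.frame(name = character(0),
                                            amplitude_cm = numeric(0),
                                            period_h = numeric(0),
                                            phase_rad = numeric(0)))),
    "constituent")
})

test_that("comparable M2 and K1 produce diurnal inequality", {
  sc <- tide_scenario(constituents = data.frame(
    name = c("M2", "K1"), amplitude_cm = c(100, 80),
    period_h = c(12.42, 23.93), phase_rad = c(0, 0.5)), span_days = 10)
  ow <- generate_open_water(sc)
  pk <- mangrovehydro:::find_peaks(ow$level_cm, 4 * 12)
  hw <- ow$level_cm[pk]
  # successive high waters alternate in height
  expect_gt(stats::median(abs(diff(hw))), 10)
})

test_that("the default mixed regime has 3-4 high tides per two lunar days", {
  ow <- generate_open_water(tide_scenario(span_days = 16))
  pk <- mangrovehydro:::find_peaks(ow$level_cm, 4 * 12)
  per_2days <- length(pk) / 8
  expect_gte(per_2days, 3)
  expect_lte(per_2days, 4)
})

test_that("free-exchange noise-free response equals the tide when flooded", {
  sc <- test_scenario(span_days = 10)
  ow <- generate_open_water(sc)
  resp <- site_response(0, noise_sd_cm = 0)  # surface at MSL
  sim <- simulate_site(ow, resp, msl_cm = sc$msl_offset_cm)
  S <- sim$truth$surface_ow_datum
  above <- ow$level_cm > S
  expect_equal(sim$series$level_cm[above], ow$level_cm[above])
  expect_true(all(sim$series$level_cm[!above] <= S + 1e-9))
})

test_that("tailing caps the ebb fall rate", {
  sc <- test_scenario(span_days = 10)
  ow <- generate_open_water(sc)
  sim <- simulate_site(ow, site_response(0, tailing_max_fall_rate = 5,
                                         noise_sd_cm = 0),
                       msl_cm = sc$msl_offset_cm)
  falls <- -diff(sim$series$level_cm) * 12  # cm/h on the 5-min grid
  expect_lte(max(falls), 5 + 1e-9)
})

test_that("capping truncates the highest tides without shortening inundation", {
  sc <- test_scenario()
  ow <- generate_open_water(sc)
  cap <- max(ow$level_cm) - 50
  sim <- simulate_site(ow, site_response(-20, cap_level_cm = cap,
                                         noise_sd_cm = 0),
                       msl_cm = sc$msl_offset_cm)
  expect_equal(max(sim$series$level_cm), cap, tolerance = 1e-9)
  # durations unaffected by capping (free outflow)
  S <- sim$truth$surface_ow_datum
  depth <- make_wls(sim$series$level_cm - S)
  obs <- summarize_inundation(extract_events(depth), series = depth)
  cf <- counterfactual_summary(ow, S)
  expect_equal(obs$min_per_day, cf$min_per_day, tolerance = 0.01)
})

test_that("noise-free free exchange conserves wet minutes vs counterfactual", {
  sc <- test_scenario()
  ow <- generate_open_water(sc)
  for (e in c(-20, 30, 90)) {
    sim <- simulate_site(ow, site_response(e, noise_sd_cm = 0),
                         msl_cm = sc$msl_offset_cm)
    S <- sim$truth$surface_ow_datum
    depth <- make_wls(sim$series$level_cm - S)
    obs <- summarize_inundation(extract_events(depth), series = depth)
    cf <- counterfactual_summary(ow, S)
    expect_equal(obs$total_min, cf$total_min)
  }
})

test_that("stronger tailing monotonically lengthens min per inundation", {
  sc <- test_scenario()
  ow <- generate_open_water(sc)
  mpi <- vapply(c(Inf, 20, 8, 3), function(rate) {
    sim <- simulate_site(ow, site_response(30, tailing_max_fall_rate = rate,
                                           noise_sd_cm = 0),
                         msl_cm = sc$msl_offset_cm)
    depth <- make_wls(sim$series$level_cm - sim$truth$surface_ow_datum)
    summarize_inundation(extract_events(depth), series = depth)$min_per_inundation
  }, numeric(1))
  expect_true(all(diff(mpi) > 0))
})

test_that("identical scenario and seed reproduce a site bit-identically", {
  sc <- test_scenario(span_days = 5)
  ow <- generate_open_water(sc)
  a <- simulate_site(ow, site_response(20), seed = 99, msl_cm = sc$msl_offset_cm)
  b <- simulate_site(ow, site_response(20), seed = 99, msl_cm = sc$msl_offset_cm)
  expect_identical(a$series$level_cm, b$series$level_cm)
})

test_that("fixture bundles round-trip and refuse accidental overwrite", {
  td <- tempfile("bundle")
  p <- preset("natural_transect")
  sc <- p$scenario
  make_fixture(td, sc, p$responses[1:2], seed = 5)
  expect_true(file.exists(file.path(td, "open_water.csv")))
  expect_true(file.exists(file.path(td, "sites.json")))
  expect_error(make_fixture(td, sc, p$responses[1:2], seed = 5), "overwrite")

  truth <- jsonlite::read_json(file.path(td, "truth.json"),
                               simplifyVector = TRUE)
  ow <- read_series(file.path(td, "open_water.csv"), datum = "open_water_local")
  for (id in names(truth)) {
    s <- read_series(file.path(td, paste0("site_", id, ".csv")),
                     datum = "open_water_local")
    surf <- normalize_to_surface(s)
    ov <- estimate_site_elevation(surf, ow)
    expect_lt(abs(ov$elevation_cm_msl - truth[[id]]$elevation_cm_msl), 2)
  }
})
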