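test_that("mean sea level is the arithmetic mean of observed levels", {
  n <- 30 * 288
  th <- (seq_len(n) - 1) / 12
  tide <- make_wls(120 + 100 * sin(2 * pi * th / 12.42),
                   datum = "open_water_local")
  expect_equal(mean_sea_level(tide), 120, tolerance = 0.5)
  const <- make_wls(rep(77.7, n), datum = "open_water_local")
  expect_equal(mean_sea_level(const), 77.7)
  ow <- generate_open_water(test_scenario())
  expect_equal(mean_sea_level(ow), mean(ow$level_cm))
  expect_warning(mean_sea_level(make_wls(rep(1, 288),
                                         datum = "open_water_local")),
                 "MSL")
})

test_that("overlay on a constructed offset series is exact", {
  ow <- generate_open_water(tide_scenario(msl_offset_cm = 0))
  site <- make_wls(ow$level_cm - 30)  # depth series of a surface at +30
  ov <- estimate_site_elevation(site, ow)
  expect_equal(ov$surface_elevation_ow_datum, 30)
  expect_equal(ov$elevation_cm_msl, 30 - mean(ow$level_cm))
  expect_equal(ov$dispersion_cm, 0)
  expect_false(ov$cap_suspected)
  expect_gte(nrow(ov$matched_peaks), 5)
})

test_that("a never-inundated site is an insufficient-overlap error", {
  ow <- generate_open_water(test_scenario())
  dry <- make_wls(rep(-5, length(ow$time)))
  expect_error(estimate_site_elevation(dry, ow), "insufficient overlap")
})

test_that("elevation recovery within 2 cm on simulated free-exchange sites", {
  sc <- test_scenario()
  ow <- generate_open_water(sc)
  set.seed(55)
  elevs <- runif(8, -40, 150)
  for (i in seq_along(elevs)) {
    sim <- simulate_site(ow, site_response(elevs[i], noise_sd_cm = 1),
                         seed = 600 + i, msl_cm = sc$msl_offset_cm)
    depth <- make_wls(sim$series$level_cm - sim$truth$surface_ow_datum)
    ov <- estimate_site_elevation(depth, ow)
    expect_lt(abs(ov$elevation_cm_msl - elevs[i]), 2)
  }
})

test_that("counterfactual inundation matches sinusoid closed forms", {
  sc <- tide_scenario(constituents = data.frame(
    name = "M2", amplitude_cm = 100, period_h = 12.42, phase_rad = 0),
    msl_offset_cm = 0)
  ow <- generate_open_water(sc)
  # elevation above the highest tide: no events
  expect_equal(counterfactual_summary(ow, 150)$n_events, 0)
  # surface at MSL: wet half the time
  f0 <- counterfactual_summary(ow, 0)$min_per_day / 1440
  expect_equal(f0, 0.5, tolerance = 0.01)
  # surface at half amplitude: acos closed form
  f50 <- counterfactual_summary(ow, 50)$min_per_day / 1440
  expect_equal(f50, acos(0.5) / pi, tolerance = 0.01)
})

test_that("counterfactual statistics are antitone in elevation", {
  ow <- generate_open_water(test_scenario())
  es <- seq(-60, 180, by = 30)
  sums <- lapply(es, function(e) counterfactual_summary(ow, mean(ow$level_cm) + e))
  mpd <- vapply(sums, `[[`, numeric(1), "min_per_day")
  expect_true(all(diff(mpd) <= 0))
})

test_that("identical observed and counterfactual regimes report no obstruction", {
  ow <- generate_open_water(test_scenario())
  cf <- counterfactual_summary(ow, mean(ow$level_cm) + 20)
  r <- obstruction_report(cf, cf)
  expect_equal(r$pct_change_min_per_day, 0)
  expect_equal(r$pct_change_min_per_inundation, 0)
  expect_equal(r$class_shift_day, 0)
  expect_false(r$tailing_flag)
  expect_false(r$capping_flag)
})

test_that("tailing inflates durations and shifts class wet-ward", {
  sc <- test_scenario()
  ow <- generate_open_water(sc)
  sim <- simulate_site(ow, site_response(40, tailing_max_fall_rate = 4,
                                         noise_sd_cm = 0.75),
                       seed = 77, msl_cm = sc$msl_offset_cm)
  S <- sim$truth$surface_ow_datum
  depth <- make_wls(sim$series$level_cm - S)
  obs <- summarize_inundation(extract_events(depth), series = depth)
  r <- obstruction_report(obs, counterfactual_summary(ow, S))
  expect_gt(r$pct_change_min_per_day, 0)
  expect_gt(r$pct_change_min_per_inundation, 0)
  expect_lt(r$class_shift_inund, 0)
  expect_true(r$tailing_flag)
})

test_that("capping is reported as a level deficit, not a duration change", {
  sc <- test_scenario()
  ow <- generate_open_water(sc)
  cap <- max(ow$level_cm) - 50
  sim <- simulate_site(ow, site_response(-20, cap_level_cm = cap,
                                         noise_sd_cm = 0.5),
                       seed = 78, msl_cm = sc$msl_offset_cm)
  S <- sim$truth$surface_ow_datum
  depth <- make_wls(sim$series$level_cm - S)
  obs <- summarize_inundation(extract_events(depth), series = depth)
  ovl <- list(surface_elevation_ow_datum = S)
  r <- obstruction_report(obs, counterfactual_summary(ow, S), site = depth,
                          ow = ow, overlay = ovl)
  expect_equal(r$capping_deficit_cm, 50, tolerance = 5)
  expect_true(r$capping_flag)
  expect_lt(abs(r$pct_change_min_per_day), 2)
})

test_that("a zero counterfactual flags the percentage as undefined", {
  ow <- generate_open_water(test_scenario())
  cf <- counterfactual_summary(ow, max(ow$level_cm) + 10)  # never flooded
  obs <- counterfactual_summary(ow, mean(ow$level_cm))
  r <- obstruction_report(obs, cf)
  expect_true(r$undefined_pct)
})

test_that("sensitivity analysis is an exact no-op at zero perturbation", {
  sc <- test_scenario()
  ow <- generate_open_water(sc)
  sim <- simulate_site(ow, site_response(30, noise_sd_cm = 0.5), seed = 80,
                       msl_cm = sc$msl_offset_cm)
  depth <- make_wls(sim$series$level_cm - sim$truth$surface_ow_datum)
  sa <- sensitivity_analysis(depth, surface_deltas_cm = 0)
  expect_equal(sa$pct_diff_day, 0)
  expect_equal(sa$pct_diff_inund, 0)
  expect_false(sa$class_changed)
})

test_that("sensitivity rows equal independent recomputation", {
  sc <- test_scenario()
  ow <- generate_open_water(sc)
  sim <- simulate_site(ow, site_response(30, noise_sd_cm = 0.5), seed = 81,
                       msl_cm = sc$msl_offset_cm)
  lev <- sim$series$level_cm - sim$truth$surface_ow_datum
  depth <- make_wls(lev)
  sa <- sensitivity_analysis(depth, surface_deltas_cm = c(-1, 1),
                             window_days = c(15, 30))
  for (i in seq_len(nrow(sa))) {
    keep <- seq_len(round(sa$window_days[i] * 288))
    wet <- (lev[keep] - sa$delta_cm[i]) > 0
    orc <- oracle_events(wet)
    total <- sum(vapply(orc, function(e) (e[2] - e[1] + 1) * 5, numeric(1)))
    expect_equal(sa$min_per_day[i], total / (length(keep) / 288))
    expect_equal(sa$min_per_inundation[i],
                 if (length(orc)) total / length(orc) else 0)
  }
  expect_warning(sensitivity_analysis(depth, 0, window_days = 60), "skip")
})
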