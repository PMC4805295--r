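# Synthetic tide and site-response generator with ground truth.
#
# The open-water signal is a sum of harmonic constituents; the default
# M2/S2/K1/O1 mix produces an irregular (mixed) semidiurnal regime with
# diurnal inequality and spring-neap modulation, and amplitudes can be
# scaled to cover tidal ranges from well under a metre to about four
# metres. The site response is deliberately phenomenological, not
# hydrodynamic: it reproduces the diagnostic signatures of obstructed
# exchange (tailing on the ebb limb, capping of the highest tides) and the
# subsurface recession below the soil surface that creates the nod point.

#' Define a tidal scenario
#'
#' @param constituents data frame with columns `name`, `amplitude_cm`,
#'   `period_h`, `phase_rad`. The default mix (M2 110, S2 40, K1 45,
#'   O1 20 cm) gives a mixed semidiurnal tide with a spring range around
#'   4 m; scale the amplitudes for smaller ranges.
#' @param msl_offset_cm mean sea level in the open-water logger datum.
#' @param span_days length of the record.
#' @param dt_min sampling interval, minutes.
#' @param start first timestamp.
#' @return A list of class `tide_scenario`.
#' @export
tide_scenario <- function(constituents = default_constituents(),
                          msl_offset_cm = 150, span_days = 30, dt_min = 5,
                          start = as.POSIXct("2011-12-20 00:00:00", tz = "UTC")) {
  stopifnot(span_days > 0)
  if (!nrow(constituents)) stop("empty constituent list")
  stopifnot(all(c("name", "amplitude_cm", "period_h", "phase_rad") %in%
                names(constituents)))
  structure(list(constituents = constituents, msl_offset_cm = msl_offset_cm,
                 span_days = span_days, dt_min = dt_min, start = start),
            class = "tide_scenario")
}

#' @rdname tide_scenario
#' @param scale multiplier applied to the default amplitudes.
#' @export
default_constituents <- function(scale = 1) {
  data.frame(
    name = c("M2", "S2", "K1", "O1"),
    amplitude_cm = scale * c(110, 40, 45, 20),
    period_h = c(12.42, 12.00, 23.93, 25.82),
    phase_rad = c(0, 0.8, 1.3, 0.4)
  )
}

#' Generate the open-water tidal series
#'
#' Deterministic harmonic synthesis on the 5-minute grid:
#' `level(t) = msl + sum_i A_i sin(2 pi t / T_i + phi_i)`.
#'
#' @param scenario a [tide_scenario()].
#' @return A [water_level_series()] (datum `"open_water_local"`).
#' @export
generate_open_water <- function(scenario) {
  stopifnot(inherits(scenario, "tide_scenario"))
  n <- round(scenario$span_days * 1440 / scenario$dt_min)
  t_h <- (seq_len(n) - 1L) * scenario$dt_min / 60
  lev <- rep(scenario$msl_offset_cm, n)
  for (i in seq_len(nrow(scenario$constituents))) {
    ci <- scenario$constituents[i, ]
    lev <- lev + ci$amplitude_cm * sin(2 * pi * t_h / ci$period_h + ci$phase_rad)
  }
  time <- scenario$start + t_h * 3600
  water_level_series(time, lev, datum = "open_water_local",
                     site_id = "open_water", dt_min = scenario$dt_min)
}

#' Define a site response
#'
#' @param elevation_cm_msl soil-surface elevation relative to the
#'   scenario's mean sea level, cm.
#' @param tailing_max_fall_rate maximum fall rate of standing water during
#'   ebb, cm/h; `Inf` means free outflow, small values mean dike-obstructed
#'   outflow (tailing).
#' @param cap_level_cm upper bound on site water level in the open-water
#'   datum; `Inf` means free inflow, finite values truncate the highest
#'   tides (capping).
#' @param subsurface_recession_rate first-order recession rate of the water
#'   table below the surface toward the groundwater floor, 1/h.
#' @param gw_floor_depth_cm depth of the groundwater floor below the
#'   surface, cm.
#' @param noise_sd_cm Gaussian sensor noise, cm (field accuracy of this
#'   class of logger is about 0.5--1 cm).
#' @return A list of class `site_response`.
#' @export
site_response <- function(elevation_cm_msl, tailing_max_fall_rate = Inf,
                          cap_level_cm = Inf, subsurface_recession_rate = 0.05,
                          gw_floor_depth_cm = 100, noise_sd_cm = 0.75) {
  if (subsurface_recession_rate <= 0) {
    stop("parameter error: subsurface_recession_rate must be positive")
  }
  structure(list(elevation_cm_msl = elevation_cm_msl,
                 tailing_max_fall_rate = tailing_max_fall_rate,
                 cap_level_cm = cap_level_cm,
                 subsurface_recession_rate = subsurface_recession_rate,
                 gw_floor_depth_cm = gw_floor_depth_cm,
                 noise_sd_cm = noise_sd_cm),
            class = "site_response")
}

#' Simulate a site's water-level response to an open-water tide
#'
#' Stepwise update in the open-water datum, with the soil surface at
#' `S = elevation + msl`: while the (possibly capped) open-water level is
#' above the site level, the site follows it; during ebb, standing water
#' drains toward the open-water level no faster than the tailing rate;
#' once below the surface, the water table recedes exponentially toward
#' the groundwater floor, producing the nod-point slope break. Gaussian
#' noise is added last.
#'
#' @param ow open-water [water_level_series()] from [generate_open_water()].
#' @param resp a [site_response()].
#' @param seed optional integer seed for the noise.
#' @param msl_cm mean sea level in the open-water datum; defaults to the
#'   mean of `ow`.
#' @return A list with `series` (the site [water_level_series()], datum
#'   `"open_water_local"`) and `truth` (elevation, surface level in the
#'   open-water datum, and the response parameters).
#' @export
simulate_site <- function(ow, resp, seed = NULL, msl_cm = mean(ow$level_cm)) {
  stopifnot(inherits(ow, "water_level_series"), inherits(resp, "site_response"))
  dt_h <- ow$dt_min / 60
  S <- resp$elevation_cm_msl + msl_cm
  floor_lev <- S - resp$gw_floor_depth_cm
  fall_step <- resp$tailing_max_fall_rate * dt_h
  decay <- exp(-resp$subsurface_recession_rate * dt_h)
  n <- length(ow$time)
  tgt <- pmin(ow$level_cm, resp$cap_level_cm)
  h <- numeric(n)
  h[1] <- max(tgt[1], S - 1)  # start at the tide or just below the surface
  for (i in 2:n) {
    prev <- h[i - 1]
    if (tgt[i] > prev) {
      h[i] <- tgt[i]
    } else {
      cand <- max(tgt[i], prev - fall_step)
      if (cand < S) {
        start <- min(prev, S)
        cand <- max(tgt[i], floor_lev + (start - floor_lev) * decay)
      }
      h[i] <- cand
    }
  }
  if (resp$noise_sd_cm > 0) {
    if (!is.null(seed)) set.seed(seed)
    h <- h + stats::rnorm(n, 0, resp$noise_sd_cm)
  }
  series <- water_level_series(ow$time, h, datum = "open_water_local",
                               site_id = "site", dt_min = ow$dt_min)
  truth <- list(elevation_cm_msl = resp$elevation_cm_msl,
                surface_ow_datum = S, msl_cm = msl_cm,
                tailing_max_fall_rate = resp$tailing_max_fall_rate,
                cap_level_cm = resp$cap_level_cm,
                subsurface_recession_rate = resp$subsurface_recession_rate,
                gw_floor_depth_cm = resp$gw_floor_depth_cm,
                noise_sd_cm = resp$noise_sd_cm)
  list(series = series, truth = truth)
}

#' Packaged simulation presets
#'
#' * `"natural_transect"` — one open-water series and six free-exchange
#'   sites on a shore-normal transect with elevations from the low
#'   intertidal (class 2) up to the rarely flooded fringe (class 4).
#' * `"obstructed_pond"` — a disused-pond setting: one free-exchange
#'   reference site, one tailing site (ebb outflow restricted to 20 cm/h,
#'   well below tidal recession rates) and one capped site whose level
#'   cannot rise within 50 cm of the highest tides.
#'
#' @param name preset name.
#' @return A list with `scenario` and a named list of `responses`.
#' @export
preset <- function(name = c("natural_transect", "obstructed_pond")) {
  name <- match.arg(name)
  sc <- tide_scenario()
  if (name == "natural_transect") {
    elev <- c(S1 = 20, S2 = 45, S3 = 80, S4 = 110, S5 = 135, S6 = 160)
    responses <- lapply(elev, function(e) site_response(e))
  } else {
    max_tide <- max(generate_open_water(sc)$level_cm)
    responses <- list(
      free = site_response(-20),
      tailing = site_response(-10, tailing_max_fall_rate = 20),
      capped = site_response(-20, cap_level_cm = max_tide - 50)
    )
  }
  list(scenario = sc, responses = responses)
}

#' Write a simulated fixture bundle to disk
#'
#' Generates the open-water series and all site responses and writes a
#' self-contained directory: `open_water.csv`, one `site_<id>.csv` per
#' site, `sites.json` (metadata and open-water pairing) and `truth.json`
#' (simulator ground truth).
#'
#' @param dir output directory.
#' @param scenario a [tide_scenario()].
#' @param responses named list of [site_response()] objects.
#' @param seed integer seed governing all noise (per-site seeds are derived
#'   from it).
#' @param overwrite refuse to touch an existing bundle unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
make_fixture <- function(dir, scenario = tide_scenario(),
                         responses = preset("natural_transect")$responses,
                         seed = 1, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    stop("bundle directory exists; use overwrite = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ow <- generate_open_water(scenario)
  write_series(ow, file.path(dir, "open_water.csv"))
  ids <- names(responses)
  if (is.null(ids) || any(!nzchar(ids))) stop("responses must be named")
  truth <- list()
  meta <- list()
  for (i in seq_along(responses)) {
    id <- ids[i]
    sim <- simulate_site(ow, responses[[i]], seed = seed + i,
                         msl_cm = scenario$msl_offset_cm)
    sim$series$site_id <- id
    write_series(sim$series, file.path(dir, paste0("site_", id, ".csv")))
    truth[[id]] <- sim$truth
    meta[[i]] <- list(site = id, role = "forest", open_water = "open_water",
                      series = paste0("site_", id, ".csv"),
                      vegetation = character(0), planted = character(0))
  }
  sites <- list(
    open_water_series = "open_water.csv",
    dt_min = scenario$dt_min,
    seed = seed,
    sites = meta
  )
  jsonlite::write_json(sites, file.path(dir, "sites.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
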