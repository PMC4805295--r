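# Orchestration: the recommended site-assessment workflow.
#
# 1. select sites and install loggers; 2. measure water levels over one or
# more ~30-day lunar tidal cycles; 3. estimate the soil surface and
# extract inundation events; 4. compute the two duration-of-inundation
# statistics and classify; 5. decide whether hydrological restoration,
# natural regeneration or planting is appropriate.

#' Run configuration
#'
#' @param series_dir directory containing the series CSVs.
#' @param sites_file site metadata: a `sites.json` bundle file (as written
#'   by [make_fixture()]) or a CSV with at least `site` and `series`
#'   columns and an `open_water` pairing column.
#' @param out_dir optional output directory for rendered reports.
#' @param nod nod-detector parameters ([nod_params()]).
#' @param k_peaks peaks used in the elevation overlay.
#' @param tailing_threshold_pct,capping_threshold_cm obstruction flags.
#' @param min_duration_min minimum event/dry-fall duration, minutes.
#' @param catalogue species catalogue for expected classes.
#' @return A list of class `run_config`.
#' @export
run_config <- function(series_dir, sites_file, out_dir = NULL,
                       nod = nod_params(), k_peaks = 5,
                       tailing_threshold_pct = 5, capping_threshold_cm = 10,
                       min_duration_min = 15,
                       catalogue = species_catalogue()) {
  if (!dir.exists(series_dir)) stop("config error: series_dir not found: ", series_dir)
  if (!file.exists(sites_file)) stop("config error: sites_file not found: ", sites_file)
  structure(list(series_dir = series_dir, sites_file = sites_file,
                 out_dir = out_dir, nod = nod, k_peaks = k_peaks,
                 tailing_threshold_pct = tailing_threshold_pct,
                 capping_threshold_cm = capping_threshold_cm,
                 min_duration_min = min_duration_min, catalogue = catalogue),
            class = "run_config")
}

read_bundle_sites <- function(sites_file) {
  if (grepl("\\.json$", sites_file)) {
    meta <- jsonlite::read_json(sites_file, simplifyVector = FALSE)
    sites <- lapply(meta$sites, function(s) {
      list(site = s$site,
           series = s$series,
           open_water = if (!is.null(s$open_water)) s$open_water else "open_water",
           vegetation = as.character(unlist(s$vegetation)),
           planted = as.character(unlist(s$planted)))
    })
    list(open_water_series = meta$open_water_series, sites = sites)
  } else {
    df <- utils::read.csv(sites_file, stringsAsFactors = FALSE)
    need <- c("site", "series", "open_water_series")
    if (!all(c("site", "series") %in% names(df))) {
      stop("config error: sites CSV needs 'site' and 'series' columns")
    }
    ow <- if ("open_water_series" %in% names(df)) df$open_water_series[1]
          else "open_water.csv"
    sites <- lapply(seq_len(nrow(df)), function(i) {
      veg <- if ("vegetation" %in% names(df) && nzchar(df$vegetation[i]))
        trimws(strsplit(df$vegetation[i], ";")[[1]]) else character(0)
      pl <- if ("planted" %in% names(df) && !is.na(df$planted[i]) &&
                nzchar(df$planted[i]))
        trimws(strsplit(df$planted[i], ";")[[1]]) else character(0)
      list(site = df$site[i], series = df$series[i], open_water = "open_water",
           vegetation = veg, planted = pl)
    })
    list(open_water_series = ow, sites = sites)
  }
}

#' Run the full assessment pipeline
#'
#' For every forest site: read the series, estimate the surface
#' ([normalize_to_surface()]), extract events, summarise, classify both
#' duration variables and combine them, estimate elevation by overlay,
#' build the free-exchange counterfactual, diagnose obstruction, derive
#' the vegetation-based expected class, and emit advice. Decisions
#' (segments, nod points, matched peaks) are kept on the per-site detail
#' objects.
#'
#' @param config a [run_config()], or a path to a fixture bundle directory
#'   (containing `sites.json`).
#' @return A list of class `site_report_set`: `table` (one row per site)
#'   and `details` (per-site intermediate objects).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!dir.exists(config)) stop("config error: no such bundle directory: ", config)
    sf <- file.path(config, "sites.json")
    if (!file.exists(sf)) stop("config error: bundle has no sites.json: ", config)
    config <- run_config(series_dir = config, sites_file = sf)
  }
  stopifnot(inherits(config, "run_config"))
  bundle <- read_bundle_sites(config$sites_file)
  if (!length(bundle$sites)) stop("config error: no sites defined")
  ow_path <- file.path(config$series_dir, bundle$open_water_series)
  if (!file.exists(ow_path)) {
    stop("config error: open-water series not found: ", ow_path)
  }
  ow <- read_series(ow_path, datum = "open_water_local")
  msl <- mean_sea_level(ow, warn_short = FALSE)
  rows <- list(); details <- list()
  for (s in bundle$sites) {
    path <- file.path(config$series_dir, s$series)
    if (!file.exists(path)) {
      stop("config error: series for site ", s$site, " not found: ", path)
    }
    raw <- read_series(path, datum = "open_water_local", site_id = s$site)
    surf <- normalize_to_surface(raw, params = config$nod)
    ev <- extract_events(surf, config$min_duration_min)
    sm <- summarize_inundation(ev, series = surf)
    cd <- classify_min_per_day(sm$min_per_day)
    ci <- classify_min_per_inundation(sm$min_per_inundation)
    comb <- combine_classes(cd, ci)
    overlay <- tryCatch(
      estimate_site_elevation(surf, ow, k = config$k_peaks),
      error = function(e) NULL)
    cf <- if (!is.null(overlay)) {
      counterfactual_summary(ow, overlay$surface_elevation_ow_datum,
                             config$min_duration_min)
    } else NULL
    obs_rep <- if (!is.null(cf)) {
      obstruction_report(sm, cf, site = surf, ow = ow, overlay = overlay,
                         tailing_threshold_pct = config$tailing_threshold_pct,
                         capping_threshold_cm = config$capping_threshold_cm)
    } else NULL
    has_veg <- length(s$vegetation) > 0
    exp_cls <- if (has_veg) {
      expected_class(s$vegetation,
                     planted = s$vegetation %in% s$planted,
                     catalogue = config$catalogue)
    } else list(label = NA, undetermined = TRUE)
    veg_lab <- if (inherits(exp_cls$label, "class_label")) exp_cls$label else NULL
    adv <- advise(comb, has_vegetation = has_veg && !is.null(veg_lab),
                  veg_class = veg_lab)
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = s$site,
      span_days = sm$span_days,
      surface_ow_cm = attr(surf, "surfaces")$surface_cm[1],
      elevation_cm_msl = if (is.null(overlay)) NA_real_ else overlay$elevation_cm_msl,
      min_per_day = sm$min_per_day,
      class_day = cd,
      min_per_inundation = sm$min_per_inundation,
      class_inund = ci,
      combined = comb$text,
      expected_veg = if (is.null(veg_lab)) NA_character_ else veg_lab$text,
      pct_change_day = if (is.null(obs_rep)) NA_real_ else obs_rep$pct_change_min_per_day,
      pct_change_inund = if (is.null(obs_rep)) NA_real_ else obs_rep$pct_change_min_per_inundation,
      tailing = if (is.null(obs_rep)) NA else obs_rep$tailing_flag,
      capping = if (is.null(obs_rep)) NA else obs_rep$capping_flag,
      advice = as.character(adv)
    )
    details[[s$site]] <- list(series = surf, events = ev, summary = sm,
                              overlay = overlay, counterfactual = cf,
                              obstruction = obs_rep, expected = exp_cls,
                              msl_cm = msl)
  }
  out <- structure(list(table = do.call(rbind, rows), details = details,
                        msl_cm = msl),
                   class = "site_report_set")
  if (!is.null(config$out_dir)) render_report(out, config$out_dir)
  out
}

#' @export
print.site_report_set <- function(x, ...) {
  cat("<site_report_set>", nrow(x$table), "site(s); MSL",
      sprintf("%.1f", x$msl_cm), "cm (open-water datum)\n")
  print(x$table[, c("site_id", "min_per_day", "class_day",
                    "min_per_inundation", "class_inund", "combined",
                    "advice")], row.names = FALSE)
  invisible(x)
}

#' Classify precomputed duration statistics
#'
#' Classification-only entry point for when the duration statistics are
#' already available (published tables, external processing), bypassing
#' the raw-series stages. Optionally derives vegetation-based expected
#' classes and advice when inventories are supplied.
#'
#' @param durations data frame with `site`, `min_per_day`,
#'   `min_per_inundation`.
#' @param sites optional site metadata (as from [survey_sites()]) with
#'   `site`, `vegetation` (list column) and `planted` (list column).
#' @param catalogue species catalogue.
#' @return A data frame with the per-variable classes, combined label, and
#'   (when metadata is given) `expected_veg` and `advice`.
#' @export
classify_durations <- function(durations, sites = NULL,
                               catalogue = species_catalogue()) {
  stopifnot(all(c("site", "min_per_day", "min_per_inundation") %in%
                names(durations)))
  out <- data.frame(
    site = durations$site,
    min_per_day = durations$min_per_day,
    class_day = classify_min_per_day(durations$min_per_day),
    min_per_inundation = durations$min_per_inundation,
    class_inund = classify_min_per_inundation(durations$min_per_inundation)
  )
  out$combined <- vapply(seq_len(nrow(out)), function(i) {
    combine_classes(out$class_day[i], out$class_inund[i])$text
  }, character(1))
  if (!is.null(sites)) {
    idx <- match(out$site, sites$site)
    out$expected_veg <- NA_character_
    out$advice <- NA_character_
    for (i in seq_len(nrow(out))) {
      j <- idx[i]
      if (is.na(j)) next
      veg <- sites$vegetation[[j]]
      pl <- sites$planted[[j]]
      has_veg <- length(veg) > 0
      exp_cls <- if (has_veg) {
        expected_class(veg, planted = veg %in% pl, catalogue = catalogue)
      } else list(label = NA, undetermined = TRUE)
      lab <- if (!exp_cls$undetermined) exp_cls$label else NULL
      out$expected_veg[i] <- if (is.null(lab)) NA_character_ else lab$text
      out$advice[i] <- as.character(
        advise(out$combined[i], has_vegetation = !is.null(lab),
               veg_class = lab))
    }
  }
  out
}

advice_text <- c(
  MONITOR = paste(
    "Vegetation is present and consistent with the hydrological class:",
    "no action needed; only monitoring that vegetation stays healthy and",
    "natural regeneration takes place."),
  ENABLE_COLONISATION = paste(
    "Hydrological conditions are suitable but no vegetation is present:",
    "obstacles (e.g. dikes) likely impede propagules. Remove the",
    "obstacles to allow natural regeneration, or plant species belonging",
    "to the estimated hydrological class."),
  RESTORE_HYDROLOGY_FIRST = paste(
    "Conditions are too wet for any mangrove species: restore the",
    "hydrological conditions first (remove dikes/weirs), then repeat the",
    "water-level measurements, re-apply the classification, and only then",
    "allow natural regeneration or plant the species of the new class."))

#' Render a report set to files
#'
#' Writes one machine-readable CSV for the whole set plus a plain-text
#' summary per site (including the advice text).
#'
#' @param reports a `site_report_set` from [run_pipeline()], or a plain
#'   data frame of classified sites.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("csv", "txt")`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(reports, dir, formats = c("csv", "txt")) {
  bad <- setdiff(formats, c("csv", "txt"))
  if (length(bad)) stop("unknown format(s): ", paste(bad, collapse = ", "))
  tab <- if (inherits(reports, "site_report_set")) reports$table else reports
  if (!nrow(tab)) stop("empty report set")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("csv" %in% formats) {
    f <- file.path(dir, "classification_report.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    written <- c(written, f)
  }
  if ("txt" %in% formats) {
    for (i in seq_len(nrow(tab))) {
      f <- file.path(dir, paste0("site_", tab$site_id[i], ".txt"))
      con <- file(f, "w")
      cat(sprintf("Site %s\n", tab$site_id[i]), file = con)
      cat(sprintf("  duration of inundation: %.0f min/day (class %s), %.0f min/inundation (class %s)\n",
                  tab$min_per_day[i], tab$class_day[i],
                  tab$min_per_inundation[i], tab$class_inund[i]), file = con)
      cat(sprintf("  combined hydrological class: %s\n", tab$combined[i]),
          file = con)
      if (!is.null(tab$expected_veg) && !is.na(tab$expected_veg[i])) {
        cat(sprintf("  expected class from vegetation: %s\n",
                    tab$expected_veg[i]), file = con)
      }
      if (!is.null(tab$elevation_cm_msl) && !is.na(tab$elevation_cm_msl[i])) {
        cat(sprintf("  elevation: %+.0f cm + MSL\n", tab$elevation_cm_msl[i]),
            file = con)
      }
      adv <- tab$advice[i]
      if (!is.na(adv)) {
        cat(sprintf("  advice [%s]: %s\n", adv, advice_text[[adv]]), file = con)
      }
      close(con)
      written <- c(written, f)
    }
  }
  invisible(written)
}
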