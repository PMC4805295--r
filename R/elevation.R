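# Elevation by high-tide overlay, counterfactual inundation, obstruction
# diagnosis and sensitivity experiments.

#' Mean sea level from an open-water series
#'
#' Operationalised as the arithmetic mean of all observed open-water
#' levels. Representative only over at least one full spring--neap cycle
#' (~30 days); shorter records yield a warning. Note this is the *local*
#' mean level: offsets of 0--15 cm against the open sea are possible in
#' deltas, and strong seasonal river discharge degrades it to a local
#' reference level only.
#'
#' @param ow open-water [water_level_series()].
#' @param warn_short warn when the record spans less than `min_days`.
#' @param min_days minimum representative span in days.
#' @return Mean level in cm (open-water datum).
#' @export
mean_sea_level <- function(ow, warn_short = TRUE, min_days = 30) {
  stopifnot(inherits(ow, "water_level_series"))
  if (length(ow$time) == 0L) stop("empty series")
  span <- observed_span_days(ow)
  if (warn_short && span < min_days - 1) {
    warning(sprintf("open-water record spans %.1f days (< %g): mean level may not represent MSL",
                    span, min_days))
  }
  mean(ow$level_cm)
}

#' Estimate site elevation by high-tide overlay
#'
#' Assumes the water surface is level between the open water and the
#' forest at maximum high tide. The `k` highest open-water peaks (at least
#' 6 h apart) are matched to the site series; at each matched peak the
#' offset open-water level minus site inundation depth estimates the soil
#' surface in the open-water datum. The median over peaks is robust to a
#' single bad peak, and the spread of per-peak offsets flags violations of
#' the level-surface assumption. Elevation relative to mean sea level is
#' the surface estimate minus [mean_sea_level()].
#'
#' @param site site [water_level_series()], datum `"surface_relative"`.
#' @param ow open-water [water_level_series()] with overlapping window.
#' @param k number of high-tide peaks to match.
#' @param min_sep_h minimum peak separation, hours.
#' @param min_peaks minimum number of co-inundated matched peaks.
#' @param min_depth_cm site must be at least this deep at a peak to count
#'   as co-inundated.
#' @param match_window_min match site samples within this many minutes of
#'   the open-water peak (0 = identical timestamps; in-forest high-tide
#'   delays are typically only minutes).
#' @param cap_tol_cm capping guard: matching is extended to the `4k`
#'   highest peaks, and when the median offset of the `k` highest matched
#'   peaks exceeds that of the `k` lowest matched peaks by more than this,
#'   the level-water assumption has failed at the highest tides (obstructed
#'   inflow truncating the peaks); the lower anchor is then used and the
#'   discrepancy reported as `cap_bias_cm`.
#' @return An object of class `overlay_result`: matched peaks, the surface
#'   level in the open-water datum, `msl_cm`, `elevation_cm_msl`, the
#'   `dispersion_cm` (standard deviation of per-peak offsets, large values
#'   flagging violations of the level-surface assumption), `cap_bias_cm`
#'   and `cap_suspected`.
#' @export
estimate_site_elevation <- function(site, ow, k = 5, min_sep_h = 6,
                                    min_peaks = 3, min_depth_cm = 2,
                                    match_window_min = 0, cap_tol_cm = 5) {
  stopifnot(inherits(site, "water_level_series"), inherits(ow, "water_level_series"))
  if (site$datum != "surface_relative") {
    stop("datum error: site series must be surface_relative (see normalize_to_surface)")
  }
  sep <- max(3L, round(min_sep_h * 60 / ow$dt_min))
  pk <- find_peaks(ow$level_cm, sep)
  if (!length(pk)) stop("no high-tide peaks found in open-water series")
  pk <- pk[order(-ow$level_cm[pk])]
  site_t <- as.numeric(site$time)
  matched <- list()
  for (p in pk) {
    if (length(matched) >= 4L * k) break
    dtv <- abs(site_t - as.numeric(ow$time[p]))
    j <- which.min(dtv)
    if (dtv[j] > match_window_min * 60 + 1e-9) next
    depth <- site$level_cm[j]
    if (depth <= min_depth_cm) next
    matched[[length(matched) + 1L]] <- data.frame(
      time = ow$time[p], ow_level_cm = ow$level_cm[p], site_depth_cm = depth,
      offset_cm = ow$level_cm[p] - depth
    )
  }
  if (length(matched) < min_peaks) {
    stop("insufficient overlap: only ", length(matched),
         " co-inundated high-tide peak(s); need ", min_peaks)
  }
  m <- do.call(rbind, matched)
  top <- m$offset_cm[seq_len(min(k, nrow(m)))]
  cap_bias <- 0
  cap_suspected <- FALSE
  surface <- stats::median(top)
  if (nrow(m) >= 2L * k) {
    low <- m$offset_cm[seq(nrow(m) - k + 1L, nrow(m))]
    cap_bias <- stats::median(top) - stats::median(low)
    if (cap_bias > cap_tol_cm) {
      cap_suspected <- TRUE
      surface <- stats::median(low)
    }
  }
  msl <- mean_sea_level(ow, warn_short = FALSE)
  structure(
    list(matched_peaks = m,
         surface_elevation_ow_datum = surface,
         msl_cm = msl,
         elevation_cm_msl = surface - msl,
         dispersion_cm = if (nrow(m) > 1) stats::sd(m$offset_cm) else 0,
         cap_bias_cm = cap_bias,
         cap_suspected = cap_suspected),
    class = "overlay_result"
  )
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf("<overlay_result> %d matched peak(s); surface %.1f cm (ow datum)\n",
              nrow(x$matched_peaks), x$surface_elevation_ow_datum))
  cat(sprintf("  MSL %.1f cm -> elevation %+.1f cm + MSL (dispersion %.2f cm)\n",
              x$msl_cm, x$elevation_cm_msl, x$dispersion_cm))
  invisible(x)
}

#' Counterfactual free-exchange inundation
#'
#' The inundation regime the site would experience with unobstructed
#' exchange: the fictitious depth series is the open-water level minus the
#' site's surface elevation (open-water datum), run through the same
#' event rules as an observed series.
#'
#' @param ow open-water [water_level_series()].
#' @param surface_elevation_ow_datum site surface level in the open-water
#'   datum, cm (from [estimate_site_elevation()]).
#' @param min_duration_min minimum event/dry-fall duration, minutes.
#' @return An `inundation_summary` (see [summarize_inundation()]).
#' @export
counterfactual_summary <- function(ow, surface_elevation_ow_datum,
                                   min_duration_min = 15) {
  stopifnot(inherits(ow, "water_level_series"))
  fict <- water_level_series(ow$time, ow$level_cm - surface_elevation_ow_datum,
                             datum = "surface_relative",
                             site_id = paste0(ow$site_id, "_counterfactual"),
                             dt_min = ow$dt_min)
  ev <- extract_events(fict, min_duration_min)
  summarize_inundation(ev, series = fict)
}

#' Diagnose flow obstruction against the counterfactual
#'
#' Compares observed inundation statistics with the free-exchange
#' counterfactual. Percentage changes are signed positive when obstruction
#' lengthens inundation (observed exceeding counterfactual). Class shifts
#' are rank(observed class) - rank(counterfactual class); negative values
#' are wet-ward shifts. Tailing (obstructed outflow) is flagged when a
#' percentage change exceeds its threshold; capping (obstructed inflow) is
#' flagged on the capping deficit, the shortfall of the observed maximum
#' inundation depth against the maximum the tide could deliver. Capping
#' truncates peaks but barely affects duration, so it is diagnosed on
#' levels, not durations.
#'
#' @param observed `inundation_summary` of the observed (surface-relative)
#'   site series.
#' @param counterfactual `inundation_summary` from
#'   [counterfactual_summary()] on the same window.
#' @param site observed surface-relative [water_level_series()] (for the
#'   capping deficit); optional.
#' @param ow open-water [water_level_series()]; optional.
#' @param overlay an `overlay_result`; optional.
#' @param tailing_threshold_pct flag tailing above this % change.
#' @param capping_threshold_cm flag capping above this deficit.
#' @return An object of class `obstruction_report`.
#' @export
obstruction_report <- function(observed, counterfactual, site = NULL, ow = NULL,
                               overlay = NULL, tailing_threshold_pct = 5,
                               capping_threshold_cm = 10) {
  pct <- function(obs, cf) {
    if (cf == 0) return(NA_real_)  # undefined-percentage flag
    100 * (obs - cf) / cf
  }
  p_day <- pct(observed$min_per_day, counterfactual$min_per_day)
  p_inund <- pct(observed$min_per_inundation, counterfactual$min_per_inundation)
  shift <- function(obs, cf, f) class_rank(f(obs)) - class_rank(f(cf))
  s_day <- shift(observed$min_per_day, counterfactual$min_per_day,
                 classify_min_per_day)
  s_inund <- shift(observed$min_per_inundation,
                   counterfactual$min_per_inundation,
                   classify_min_per_inundation)
  deficit <- NA_real_
  if (!is.null(site) && !is.null(ow) && !is.null(overlay)) {
    deficit <- (max(ow$level_cm) - overlay$surface_elevation_ow_datum) -
      max(site$level_cm)
  }
  structure(
    list(pct_change_min_per_day = p_day,
         pct_change_min_per_inundation = p_inund,
         undefined_pct = is.na(p_day) || is.na(p_inund),
         class_shift_day = s_day,
         class_shift_inund = s_inund,
         capping_deficit_cm = deficit,
         tailing_flag = isTRUE(p_day > tailing_threshold_pct) ||
                        isTRUE(p_inund > tailing_threshold_pct),
         capping_flag = isTRUE(deficit > capping_threshold_cm),
         tailing_threshold_pct = tailing_threshold_pct,
         capping_threshold_cm = capping_threshold_cm),
    class = "obstruction_report"
  )
}

#' @export
print.obstruction_report <- function(x, ...) {
  cat(sprintf("<obstruction_report> d(min/day) %+.1f%%  d(min/inund) %+.1f%%\n",
              x$pct_change_min_per_day, x$pct_change_min_per_inundation))
  cat(sprintf("  class shift (day/inund): %+d / %+d; capping deficit: %s cm\n",
              x$class_shift_day, x$class_shift_inund,
              if (is.na(x$capping_deficit_cm)) "NA" else
                sprintf("%.1f", x$capping_deficit_cm)))
  cat("  tailing:", x$tailing_flag, " capping:", x$capping_flag, "\n")
  invisible(x)
}

#' Sensitivity of inundation statistics to surface level and window
#'
#' Recomputes both duration statistics and classes after perturbing the
#' surface estimate (shifting the whole series) and/or truncating the
#' record to shorter windows, and reports percentage differences and class
#' stability against the unperturbed full-window baseline. Windows longer
#' than the record are skipped with a warning.
#'
#' @param series surface-relative [water_level_series()].
#' @param surface_deltas_cm surface perturbations in cm (positive = the
#'   surface estimate raised, so depths reduced).
#' @param window_days record truncations in days (`NULL` = full record
#'   only).
#' @param min_duration_min minimum event/dry-fall duration.
#' @return A data frame with one row per (delta, window) combination:
#'   the statistics, their % differences vs baseline, the classes, and
#'   `class_changed`.
#' @export
sensitivity_analysis <- function(series, surface_deltas_cm = c(-1, 0, 1),
                                 window_days = NULL, min_duration_min = 15) {
  stopifnot(inherits(series, "water_level_series"),
            series$datum == "surface_relative")
  full_days <- observed_span_days(series)
  windows <- if (is.null(window_days)) full_days else window_days
  ok <- windows <= full_days + 1e-9
  if (any(!ok)) {
    warning("skipping window(s) longer than the record: ",
            paste(windows[!ok], collapse = ", "), " d")
    windows <- windows[ok]
  }
  stat_for <- function(delta, wdays) {
    keep <- series$time < series$time[1] + wdays * 86400
    s <- water_level_series(series$time[keep], series$level_cm[keep] - delta,
                            datum = "surface_relative", site_id = series$site_id,
                            dt_min = series$dt_min)
    summarize_inundation(extract_events(s, min_duration_min), series = s)
  }
  base <- stat_for(0, full_days)
  rows <- list()
  for (d in surface_deltas_cm) for (w in windows) {
    sm <- stat_for(d, w)
    rows[[length(rows) + 1L]] <- data.frame(
      delta_cm = d, window_days = w,
      min_per_day = sm$min_per_day,
      min_per_inundation = sm$min_per_inundation,
      pct_diff_day = 100 * (sm$min_per_day - base$min_per_day) /
        base$min_per_day,
      pct_diff_inund = if (base$min_per_inundation > 0)
        100 * (sm$min_per_inundation - base$min_per_inundation) /
          base$min_per_inundation else NA_real_,
      class_day = classify_min_per_day(sm$min_per_day),
      class_inund = classify_min_per_inundation(sm$min_per_inundation),
      class_changed =
        classify_min_per_day(sm$min_per_day) !=
          classify_min_per_day(base$min_per_day) ||
        classify_min_per_inundation(sm$min_per_inundation) !=
          classify_min_per_inundation(base$min_per_inundation)
    )
  }
  do.call(rbind, rows)
}
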