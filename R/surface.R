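# Soil-surface estimation from ebb recession limbs.
#
# At ebb the measured level falls at the tidal rate while water stands on
# the surface; once the water table passes below the surface, drainage is
# governed by much slower subsurface flow. The slope break ("nod point") on
# each recession limb therefore marks the soil surface in the logger's
# datum. We locate it with a two-segment continuous piecewise-linear least
# squares fit over candidate breakpoints.

#' Nod-point detector parameters
#'
#' @param smooth_k width (odd, samples) of the running median used for
#'   peak/limb finding; the fit itself runs on raw levels.
#' @param min_peak_sep_h minimum separation between high-tide peaks, hours.
#' @param min_prominence_cm minimum drop from peak to following trough for
#'   a limb to be considered.
#' @param peak_trim_frac fraction of the peak-to-trough range trimmed from
#'   the (flat) top of the limb before fitting.
#' @param tail_window_min how far past the current breakpoint estimate the
#'   fitted window extends; limits the influence of the curved subsurface
#'   tail.
#' @param max_iter maximum breakpoint refinement passes.
#' @param slope_ratio_max a break is accepted only when the magnitude of
#'   the post-break slope is below this fraction of the pre-break slope.
#' @param min_f_ratio minimum F-like variance-ratio improvement of the
#'   two-segment over the one-segment fit.
#' @param min_limb_samples minimum samples on a limb.
#' @return A named list of parameters.
#' @export
nod_params <- function(smooth_k = 9, min_peak_sep_h = 4, min_prominence_cm = 20,
                       peak_trim_frac = 0.15, tail_window_min = 90,
                       max_iter = 5, slope_ratio_max = 0.25, min_f_ratio = 15,
                       min_limb_samples = 8) {
  list(smooth_k = smooth_k, min_peak_sep_h = min_peak_sep_h,
       min_prominence_cm = min_prominence_cm, peak_trim_frac = peak_trim_frac,
       tail_window_min = tail_window_min, max_iter = max_iter,
       slope_ratio_max = slope_ratio_max, min_f_ratio = min_f_ratio,
       min_limb_samples = min_limb_samples)
}

# Local maxima of a smoothed level vector, thinned to a minimum separation
# (keeping the higher peak of any close pair).
find_peaks <- function(level, min_sep_samples, smooth_k = 9) {
  s <- if (length(level) >= smooth_k) stats::runmed(level, smooth_k) else level
  d <- diff(s)
  # candidate peaks: rises followed by falls (plateaus collapse to first max)
  up <- d > 0
  cand <- which(diff(c(FALSE, up)) == -1)
  cand <- cand[cand > 1 & cand < length(level)]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-s[cand])]
  keep <- integer(0)
  for (p in cand) {
    if (!length(keep) || all(abs(keep - p) >= min_sep_samples)) keep <- c(keep, p)
  }
  sort(keep)
}

# Index ranges (peak .. trough-before-next-rise) of recession limbs.
recession_limbs <- function(series, params) {
  lev <- series$level_cm
  n <- length(lev)
  dt <- series$dt_min
  sep <- max(3L, round(params$min_peak_sep_h * 60 / dt))
  s <- if (n >= params$smooth_k) stats::runmed(lev, params$smooth_k) else lev
  peaks <- find_peaks(lev, sep, params$smooth_k)
  if (!length(peaks)) return(list())
  limbs <- list()
  bounds <- c(peaks, n)
  for (i in seq_along(peaks)) {
    a <- peaks[i]; b <- bounds[i + 1L]
    if (b - a + 1L < params$min_limb_samples) next
    seg <- s[a:b]
    tr <- a + which.min(seg) - 1L         # trough before next rise
    if (tr - a + 1L < params$min_limb_samples) next
    drop <- s[a] - s[tr]
    if (drop < params$min_prominence_cm) next
    # trim the flat crest of the limb
    cut <- s[a] - params$peak_trim_frac * drop
    st <- a + which(s[a:tr] <= cut)[1] - 1L
    if (is.na(st) || tr - st + 1L < params$min_limb_samples) next
    limbs[[length(limbs) + 1L]] <- c(st, tr)
  }
  limbs
}

# Continuous two-segment least-squares fit with the break at sample k.
# Returns SSE and the two slopes plus the fitted level at the break.
fit_break_at <- function(x, y, k) {
  X <- cbind(1, x, pmax(x - x[k], 0))
  b <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, 3))
  if (anyNA(b)) return(NULL)
  res <- y - X %*% b
  list(sse = sum(res^2), slope1 = b[2], slope2 = b[2] + b[3],
       level = b[1] + b[2] * x[k])
}

# Best two-segment fit over interior candidate breakpoints.
best_break <- function(x, y) {
  n <- length(x)
  ks <- 3:(n - 2)
  best <- NULL
  for (k in ks) {
    f <- fit_break_at(x, y, k)
    if (is.null(f)) next
    if (is.null(best) || f$sse < best$sse) { best <- f; best$k <- k }
  }
  best
}

#' Detect nod points on recession limbs
#'
#' Scans the series for high-tide peaks, takes each recession limb (peak to
#' the trough before the next rise) and fits a continuous two-segment
#' piecewise-linear model by least squares over candidate breakpoints. The
#' window below the break is limited to `tail_window_min` minutes and the
#' breakpoint refined iteratively, so that the curved subsurface tail does
#' not drag the fit. A break is accepted when the post-break slope is much
#' flatter than the pre-break (tidal) slope and the two-segment fit beats a
#' straight line by an F-like variance ratio; limbs without a detectable
#' slope change yield no nod point.
#'
#' @param series a [water_level_series()] (datum `"open_water_local"`).
#' @param params a [nod_params()] list.
#' @return A data frame with one row per accepted nod point: `time`,
#'   `level_cm`, `recession_id`, `f_ratio`, `slope_ratio`.
#' @export
detect_nod_points <- function(series, params = nod_params()) {
  stopifnot(inherits(series, "water_level_series"))
  dt <- series$dt_min
  limbs <- recession_limbs(series, params)
  if (!length(limbs)) {
    if (length(series$time) * dt < 6 * 60) {
      stop("insufficient data: series shorter than one recession limb")
    }
    return(empty_nods())
  }
  tail_n <- max(3L, round(params$tail_window_min / dt))
  out <- list()
  for (i in seq_along(limbs)) {
    a <- limbs[[i]][1]; b <- limbs[[i]][2]
    idx <- a:b
    x <- as.numeric(series$time[idx] - series$time[a], units = "mins")
    y <- series$level_cm[idx]
    n <- length(x)
    # one-segment baseline
    X1 <- cbind(1, x)
    r1 <- y - X1 %*% qr.coef(qr(X1), y)
    sse1_full <- sum(r1^2)
    if (sse1_full < 1e-8 * n) next  # already linear: no slope change exists
    # iterative breakpoint refinement with a limited subsurface window
    hi <- n
    fit <- NULL
    for (it in seq_len(params$max_iter)) {
      fit <- best_break(x[1:hi], y[1:hi])
      if (is.null(fit)) break
      hi_new <- min(n, fit$k + tail_n)
      if (hi_new >= hi || hi_new < params$min_limb_samples) break
      hi <- hi_new
    }
    if (is.null(fit)) next
    m <- hi
    X1 <- cbind(1, x[1:m]); r1 <- y[1:m] - X1 %*% qr.coef(qr(X1), y[1:m])
    sse1 <- sum(r1^2)
    if (sse1 < 1e-8 * m) next
    f_ratio <- if (fit$sse <= 1e-12) Inf else
      ((sse1 - fit$sse) / 2) / (fit$sse / max(1, m - 4))
    slope_ratio <- abs(fit$slope2) / max(abs(fit$slope1), 1e-12)
    if (fit$slope1 >= 0) next
    if (slope_ratio > params$slope_ratio_max) next
    if (f_ratio < params$min_f_ratio) next
    out[[length(out) + 1L]] <- data.frame(
      time = series$time[a + fit$k - 1L],
      level_cm = fit$level,
      recession_id = i,
      f_ratio = f_ratio,
      slope_ratio = slope_ratio
    )
  }
  if (!length(out)) return(empty_nods())
  do.call(rbind, out)
}

empty_nods <- function() {
  data.frame(time = as.POSIXct(character(0), tz = "UTC"), level_cm = numeric(0),
             recession_id = integer(0), f_ratio = numeric(0),
             slope_ratio = numeric(0))
}

#' Partition a series at reference-level changes
#'
#' The logger's reference level can change when the instrument is lifted
#' for readout (service) or when the surface around the tube is disturbed.
#' The series is split at declared service times (always honoured, even
#' without a visible jump) and at detected discontinuities: an
#' adjacent-sample level jump larger than `jump_cm` occurring in otherwise
#' quiet (slowly varying, i.e. dry/recession) conditions.
#'
#' @param series a [water_level_series()].
#' @param service_times optional `POSIXct` instants of known services.
#' @param jump_cm minimum absolute adjacent-sample jump to flag.
#' @param quiet_window samples on each side used to judge local quietness.
#' @param quiet_frac the local median absolute step must be below this
#'   fraction of the jump.
#' @param min_segment_samples detected jumps closer than this to the series
#'   ends or to another boundary are ignored (declared service times are
#'   always honoured); a genuine reference segment spans at least a day.
#' @return A data frame with one row per segment: `segment`, `from_idx`,
#'   `to_idx`, `from`, `to`, `cause` of the boundary that opened it.
#' @export
segment_reference <- function(series, service_times = NULL, jump_cm = 5,
                              quiet_window = 6, quiet_frac = 0.25,
                              min_segment_samples = 288) {
  stopifnot(inherits(series, "water_level_series"))
  n <- length(series$time)
  lev <- series$level_cm
  d <- diff(lev)
  cuts <- integer(0); causes <- character(0)
  cand <- which(abs(d) > jump_cm)
  for (i in cand) {
    bi <- intersect((i - quiet_window):(i - 1L), seq_len(n - 1L))
    ai <- intersect((i + 1L):(i + quiet_window), seq_len(n - 1L))
    if (!length(bi) || !length(ai)) next
    # a reference jump happens in quiet (dry) conditions on BOTH sides;
    # a tidal wetting/drying front has an active limb on one side
    if (stats::median(abs(d[bi])) >= quiet_frac * abs(d[i]) ||
        stats::median(abs(d[ai])) >= quiet_frac * abs(d[i])) next
    # and the offset persists: a one-sample noise spike shifts nothing.
    # The median level shift across the candidate is detrended by the
    # pre-jump recession slope before comparison.
    lag <- mean(ai + 1L) - mean(bi)
    shift <- stats::median(lev[ai + 1L]) - stats::median(lev[bi]) -
      lag * stats::median(d[bi])
    if (abs(shift) < 0.6 * abs(d[i]) || sign(shift) != sign(d[i])) next
    cuts <- c(cuts, i + 1L); causes <- c(causes, "jump")
  }
  if (!is.null(service_times)) {
    for (st in as.list(service_times)) {
      j <- which(series$time >= st)[1]
      if (!is.na(j) && j > 1L && j <= n) {
        cuts <- c(cuts, j); causes <- c(causes, "service")
      }
    }
  }
  o <- order(cuts)
  cuts <- cuts[o]; causes <- causes[o]
  keep <- !duplicated(cuts)
  cuts <- cuts[keep]; causes <- causes[keep]
  # drop detected jumps that would open an implausibly short segment
  ok <- rep(TRUE, length(cuts))
  last <- 1L
  for (j in seq_along(cuts)) {
    short <- cuts[j] - last < min_segment_samples ||
      n + 1L - cuts[j] < min_segment_samples
    if (short && causes[j] == "jump") { ok[j] <- FALSE; next }
    last <- cuts[j]
  }
  cuts <- cuts[ok]; causes <- causes[ok]
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, n)
  data.frame(
    segment = seq_along(starts),
    from_idx = starts, to_idx = ends,
    from = series$time[starts], to = series$time[ends],
    cause = c("start", causes)
  )
}

#' Normalise a series to the soil-surface datum
#'
#' Splits the series into reference segments ([segment_reference()]),
#' detects nod points per segment ([detect_nod_points()]), aggregates them
#' by the median (robust to disturbed limbs) and subtracts the per-segment
#' surface estimate, so the soil surface sits at 0 cm.
#'
#' @param series a [water_level_series()] with datum `"open_water_local"`.
#' @param service_times optional known service instants.
#' @param params [nod_params()].
#' @param segments optional precomputed segment table.
#' @param nod_points optional precomputed nod table (must contain rows in
#'   every segment).
#' @return A [water_level_series()] with datum `"surface_relative"`, with
#'   attributes `surfaces` (per-segment estimates: `segment`, `surface_cm`,
#'   `n_nod`) and `nod_points`.
#' @export
normalize_to_surface <- function(series, service_times = NULL,
                                 params = nod_params(), segments = NULL,
                                 nod_points = NULL) {
  stopifnot(inherits(series, "water_level_series"))
  if (series$datum == "surface_relative") return(series)
  if (is.null(segments)) segments <- segment_reference(series, service_times)
  lev <- series$level_cm
  surfaces <- data.frame(segment = segments$segment,
                         surface_cm = NA_real_, n_nod = 0L)
  nods_all <- list()
  for (i in seq_len(nrow(segments))) {
    idx <- segments$from_idx[i]:segments$to_idx[i]
    nd <- if (is.null(nod_points)) {
      sub <- water_level_series(series$time[idx], series$level_cm[idx],
                                datum = series$datum, site_id = series$site_id,
                                dt_min = series$dt_min)
      tryCatch(detect_nod_points(sub, params), error = function(e) empty_nods())
    } else {
      nod_points[nod_points$time >= segments$from[i] &
                 nod_points$time <= segments$to[i], , drop = FALSE]
    }
    if (!nrow(nd)) {
      stop("no nod points found in segment ", segments$segment[i],
           " (", format(segments$from[i]), " .. ", format(segments$to[i]), ")")
    }
    surf <- stats::median(nd$level_cm)
    surfaces$surface_cm[i] <- surf
    surfaces$n_nod[i] <- nrow(nd)
    lev[idx] <- lev[idx] - surf
    nd$segment <- segments$segment[i]
    nods_all[[i]] <- nd
  }
  out <- water_level_series(series$time, lev, datum = "surface_relative",
                            site_id = series$site_id, dt_min = series$dt_min)
  attr(out, "surfaces") <- surfaces
  attr(out, "nod_points") <- do.call(rbind, nods_all)
  attr(out, "segments") <- segments
  out
}
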