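# Ordinal hydrological class scale and threshold classifiers.
#
# Sites are placed on a six-step ordinal scale 1 < 2 < 2* < 3 < 4 < 5 from
# wettest (mudflat, inundated too often for any mangrove) to driest (almost
# never inundated). Class 2* is the wetter half of the classical class 3,
# split off because species turnover is sharpest around mid-intertidal
# elevations.

#' The ordinal class scale
#'
#' Class labels from wettest to driest. Rank 1 corresponds to label "1"
#' (wettest), rank 6 to label "5" (driest); "2*" sits between "2" and "3".
#'
#' @export
hydro_levels <- c("1", "2", "2*", "3", "4", "5")

#' Convert between class labels and ordinal ranks
#'
#' @param label character class label(s) from [hydro_levels].
#' @return `class_rank()` returns integer rank(s) 1..6 (1 = wettest);
#'   `rank_to_label()` the inverse.
#' @export
class_rank <- function(label) {
  r <- match(label, hydro_levels)
  if (anyNA(r)) stop("unknown class label: ", paste(label[is.na(r)], collapse = ", "))
  r
}

#' @rdname class_rank
#' @param rank integer rank(s) 1..6.
#' @export
rank_to_label <- function(rank) {
  if (any(rank < 1 | rank > 6)) stop("rank out of range 1..6")
  hydro_levels[rank]
}

# Shared interval classifier: duration intervals are upper-inclusive on the
# wet side, i.e. class k covers (lo, hi]. Forced by the printed boundary
# case 800 min/day -> class 2; a duration of exactly 10 min/day is class 5
# under the same convention.
classify_duration <- function(d, bounds) {
  if (any(d < 0)) stop("domain error: negative duration")
  # bounds: descending upper bounds for classes 1..5 boundaries
  labs <- hydro_levels
  vapply(d, function(x) {
    if (x > bounds[1]) labs[1]
    else if (x > bounds[2]) labs[2]
    else if (x > bounds[3]) labs[3]
    else if (x > bounds[4]) labs[4]
    else if (x > bounds[5]) labs[5]
    else labs[6]
  }, character(1))
}

#' Classify duration of inundation in minutes per day
#'
#' Thresholds (upper-inclusive): class 1 above 800; 2 in (400, 800];
#' 2* in (250, 400]; 3 in (150, 250]; 4 in (10, 150]; 5 at or below 10.
#'
#' @param d duration of inundation in minutes per day (vectorised).
#' @return Character class label(s).
#' @export
classify_min_per_day <- function(d) {
  classify_duration(d, c(800, 400, 250, 150, 10))
}

#' Classify duration of inundation in minutes per inundation
#'
#' Thresholds (upper-inclusive): class 1 above 600; 2 in (450, 600];
#' 2* in (200, 450]; 3 in (100, 200]; 4 in (50, 100]; 5 at or below 50.
#'
#' @param d duration of inundation in minutes per inundation event
#'   (vectorised).
#' @return Character class label(s).
#' @export
classify_min_per_inundation <- function(d) {
  classify_duration(d, c(600, 450, 200, 100, 50))
}

#' Classify by elevation relative to mean sea level
#'
#' Elevation is only a proxy for inundation in regions with regular tides
#' and a regular elevation profile; direct water-level measurement is
#' preferred. Intervals are lower-inclusive: class 1 below 0 cm; 2 in
#' \[0, 50); 2* in \[50, 100); 3 in \[100, 150); 4 in \[150, 210); 5 at or
#' above 210 cm + MSL.
#'
#' @param e elevation in cm relative to mean sea level (vectorised).
#' @return Character class label(s).
#' @export
classify_elevation <- function(e) {
  vapply(e, function(x) {
    if (x < 0) "1"
    else if (x < 50) "2"
    else if (x < 100) "2*"
    else if (x < 150) "3"
    else if (x < 210) "4"
    else "5"
  }, character(1))
}

#' Classic flooding-frequency classifier
#'
#' The original five-class scheme keyed on flooding frequency in floods
#' per month (lower-inclusive): class 1 for 56--62, 2 for 45--56, 3 for
#' 20--45, 4 for 2--20, 5 below 2. Frequencies above 62 are outside the
#' table and map to class 1 with a warning. Unsuitable for mixed/irregular
#' tidal regimes; provided for comparison only.
#'
#' @param freq flooding frequency in floods per month (vectorised).
#' @return Integer class(es) 1..5.
#' @export
classify_watson <- function(freq) {
  if (any(freq < 0)) stop("domain error: negative frequency")
  vapply(freq, function(f) {
    if (f > 62) {
      warning("flooding frequency ", f, " above tabulated range (62/month)")
      return(1L)
    }
    if (f >= 56) 1L
    else if (f >= 45) 2L
    else if (f >= 20) 3L
    else if (f >= 2) 4L
    else 5L
  }, integer(1))
}

#' Combined class label
#'
#' A label on the class scale that is either a single class, a range of two
#' adjacent classes in wet-to-dry order (e.g. "1-2"), or an alternative
#' between classes (e.g. "2*/3").
#'
#' @param classes character vector of 1 or 2 class labels (wet-to-dry).
#' @param kind one of "single", "range", "alternative".
#' @param warning_flag logical; set when the combination was inconsistent.
#' @return An object of class `class_label` with fields `kind`, `classes`,
#'   `text`, `warning`.
#' @export
class_label <- function(classes, kind = c("single", "range", "alternative"),
                        warning_flag = FALSE) {
  kind <- match.arg(kind)
  r <- class_rank(classes)
  classes <- classes[order(r)]
  text <- switch(kind,
    single = classes[1],
    range = paste(classes, collapse = "-"),
    alternative = paste(classes, collapse = "/"))
  structure(list(kind = kind, classes = classes, text = text,
                 warning = warning_flag),
            class = "class_label")
}

#' @export
print.class_label <- function(x, ...) {
  cat(x$text, if (x$warning) " [inconsistent]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.class_label <- function(x, ...) x$text

#' Parse a combined class label from text
#'
#' @param text e.g. `"2*"`, `"1-2"`, `"2*/3"`.
#' @return A [class_label()].
#' @export
parse_class_label <- function(text) {
  text <- trimws(text)
  if (grepl("/", text, fixed = TRUE)) {
    class_label(strsplit(text, "/", fixed = TRUE)[[1]], "alternative")
  } else if (text %in% hydro_levels) {
    class_label(text, "single")
  } else if (grepl("-", text, fixed = TRUE)) {
    # careful: "2-2*" splits as c("2","2*")
    parts <- strsplit(text, "-", fixed = TRUE)[[1]]
    class_label(parts, "range")
  } else {
    stop("cannot parse class label '", text, "'")
  }
}

#' Combine the classes of the two duration variables
#'
#' The two duration-of-inundation classifiers can disagree; the combined
#' ("average") class is: the common class when they agree; the wet-to-dry
#' range label when ranks differ by one; the middle class when ranks differ
#' by two; and the range of the two extremes, flagged inconsistent, when
#' they differ by more.
#'
#' @param c1,c2 class labels (order immaterial).
#' @return A [class_label()].
#' @export
combine_classes <- function(c1, c2) {
  r <- sort(class_rank(c(c1, c2)))
  d <- r[2] - r[1]
  if (d == 0) {
    class_label(rank_to_label(r[1]), "single")
  } else if (d == 1) {
    class_label(rank_to_label(r), "range")
  } else if (d == 2) {
    class_label(rank_to_label(r[1] + 1L), "single")
  } else {
    class_label(rank_to_label(r), "range", warning_flag = TRUE)
  }
}

#' Management advice for a restoration site
#'
#' Three-way advice keyed on the hydrological class and the vegetation:
#'
#' * `RESTORE_HYDROLOGY_FIRST` — conditions too wet for any mangrove
#'   (hydrological class 1): restore the hydrology (remove dikes/weirs),
#'   re-measure, re-classify, then regenerate or plant.
#' * `ENABLE_COLONISATION` — suitable hydrology but no vegetation:
#'   something other than hydrology (often dikes blocking propagules)
#'   prevents establishment; remove obstacles for natural regeneration or
#'   plant species of the estimated class.
#' * `MONITOR` — vegetation present and broadly consistent with the
#'   hydrological class (overlapping or adjacent): no action beyond
#'   monitoring health and regeneration.
#'
#' @param hydro combined hydrological class ([class_label()] or text).
#' @param has_vegetation logical, vegetation present at the site.
#' @param veg_class expected class from vegetation ([class_label()] or
#'   text); required when `has_vegetation` is `TRUE`.
#' @return Character advice category with attribute `match` (logical; for
#'   `MONITOR`, whether vegetation and hydrology classes overlap/abut).
#' @export
advise <- function(hydro, has_vegetation, veg_class = NULL) {
  if (is.character(hydro)) hydro <- parse_class_label(hydro)
  hr <- class_rank(hydro$classes)
  too_wet <- all(hr == 1L)   # single class "1"
  if (too_wet) {
    return(structure("RESTORE_HYDROLOGY_FIRST", match = NA))
  }
  if (!has_vegetation) {
    return(structure("ENABLE_COLONISATION", match = NA))
  }
  if (is.null(veg_class)) stop("vegetation present but no vegetation class given")
  if (is.character(veg_class)) veg_class <- parse_class_label(veg_class)
  vr <- class_rank(veg_class$classes)
  gap <- min(abs(outer(hr, vr, "-")))
  structure("MONITOR", match = gap <= 1)
}
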