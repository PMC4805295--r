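# Packaged reference survey of 23 intertidal sites.
#
# The bundled tables describe a field survey of 15 natural and 8
# hydrologically disturbed (disused shrimp-pond) mangrove sites in seven
# locations (A-G) across three estuarine regions of southeast Asia:
# per-site metadata with elevation and a vegetation inventory in dominance
# order, the measured duration-of-inundation statistics with the resulting
# classes, and the elevation-only classification used for comparison. The
# original raw logger series were never deposited; these summary tables
# are the reference surface for the classification layer.

#' Reference survey: site metadata
#'
#' @return A data frame with one row per site: `location`, `site`, `start`,
#'   `end` (measurement window, dates), `elevation_cm_msl`, `distance_m`
#'   (to the main channel/sea; `NA` when at the coast), `disturbed`,
#'   `vegetation` (list column, dominance order; empty for bare sites),
#'   `planted` (list column of planted species) and `role` (all
#'   `"forest"`).
#' @export
survey_sites <- function() {
  path <- system.file("extdata", "survey_sites.csv",
                      package = "mangrovehydro", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_field <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  df$vegetation <- split_field(df$vegetation)
  df$planted <- split_field(df$planted)
  df$start <- as.Date(df$start)
  df$end <- as.Date(df$end)
  df$role <- "forest"
  df
}

#' Reference survey: measured inundation durations and classes
#'
#' @return A data frame with `site`, the two measured duration statistics
#'   (`min_per_day`, `min_per_inundation`), the published per-variable
#'   classes (`class_day`, `class_inund`), the combined `average_class`
#'   and the vegetation-based `expected_class` (`NA` for bare sites).
#' @export
survey_durations <- function() {
  path <- system.file("extdata", "survey_durations.csv",
                      package = "mangrovehydro", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$min_per_day <- as.numeric(df$min_per_day)
  df$min_per_inundation <- as.numeric(df$min_per_inundation)
  df$expected_class[!nzchar(df$expected_class)] <- NA_character_
  df
}

#' Reference survey: elevation-only classification
#'
#' @return A data frame with `site`, the published class obtained from
#'   elevation alone (`class_elevation_only`) and, for disturbed sites, the
#'   elevation-matched natural `paired_site`.
#' @export
survey_elevation_classes <- function() {
  path <- system.file("extdata", "elevation_only_classes.csv",
                      package = "mangrovehydro", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$paired_site[!nzchar(df$paired_site)] <- NA_character_
  df
}
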