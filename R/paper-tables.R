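## Published Balkan Griffon Vulture reference tables, bundled as plain CSV
## under inst/extdata. These are the printed per-bird tracking summaries
## and per-zone/seasonal statistics for the 2016-2021 Balkan tracking
## programme; the raw telemetry itself was never deposited, so these
## tables are the recomputation inputs for the cohort statistics.

refPath <- function(file) {
  p <- system.file("extdata", file, package = "griffonRanges")
  if (!nzchar(p)) stop("bundled file not found: ", file)
  p
}

#' Bundled per-bird tracking summary (Balkan Griffon Vultures)
#'
#' One row per tagged bird: tag, transmitter, tagging location, capture
#' group, tracking period, number of GPS fixes received on the Balkans,
#' tracked days used in calculations, and the 50% core-area and 95%
#' home-range sizes (km^2). Birds tracked for fewer than 50 days carry
#' `NA` areas -- they were excluded from the range analysis.
#'
#' @param usedOnly drop the excluded short-tracked birds (default `TRUE`).
#' @return data.frame.
#' @export
griffonBirds <- function(usedOnly = TRUE) {
  d <- read.csv(refPath("balkan_griffon_birds.csv"),
                stringsAsFactors = FALSE)
  if (usedOnly) d <- d[!is.na(d$homerange95_km2), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Bundled seasonal range statistics
#'
#' Published per-season summary (n bird-seasons, mean/median/sd/min/max of
#' 50% core areas and 95% home ranges, km^2).
#'
#' @return data.frame, one row per season.
#' @export
griffonSeasonalStats <- function() {
  read.csv(refPath("balkan_seasonal_stats.csv"), stringsAsFactors = FALSE)
}

#' Bundled vulture key zone statistics
#'
#' Published per-zone bird counts and 50%/95% areas (km^2) for the seven
#' Balkan vulture key zones.
#'
#' @return data.frame, one row per zone.
#' @export
griffonZoneStats <- function() {
  read.csv(refPath("balkan_zone_stats.csv"), stringsAsFactors = FALSE)
}

#' Cohort tracking summary
#'
#' Aggregates a per-bird tracking table (fix and day counts per bird) into
#' the headline cohort figures: total fixes, total tracked days, mean and
#' spread of positions per bird, fixes per tracked day, and mean tracking
#' days.
#'
#' @param birds data.frame with columns `gps_fixes` and `tracking_days`
#'   (one row per bird), e.g. [griffonBirds()].
#' @return named list of summary values.
#' @export
trackingSummary <- function(birds) {
  stopifnot(all(c("gps_fixes", "tracking_days") %in% names(birds)))
  n <- nrow(birds)
  tf <- sum(birds$gps_fixes)
  td <- sum(birds$tracking_days)
  list(n_birds = n,
       total_fixes = tf,
       total_days = td,
       mean_fixes_per_bird = tf / n,
       sd_fixes_per_bird = sd(birds$gps_fixes),
       min_fixes_per_bird = min(birds$gps_fixes),
       max_fixes_per_bird = max(birds$gps_fixes),
       fixes_per_day = tf / td,
       mean_tracking_days = td / n,
       sd_tracking_days = sd(birds$tracking_days),
       min_tracking_days = min(birds$tracking_days),
       max_tracking_days = max(birds$tracking_days))
}
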