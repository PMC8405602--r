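## Diurnal/seasonal partitioning. The transmitters operate on a fixed
## UTC+2 clock; the analysis window and season boundaries are civil-clock
## conventions, so no daylight-saving or sunrise modelling is involved.

localTime <- function(timestamp, utcOffset = 2) {
  timestamp + utcOffset * 3600
}

localDate <- function(timestamp, utcOffset = 2) {
  as.Date(localTime(timestamp, utcOffset), tz = "UTC")
}

localHour <- function(timestamp, utcOffset = 2) {
  lt <- localTime(timestamp, utcOffset)
  as.numeric(format(lt, "%H", tz = "UTC")) +
    as.numeric(format(lt, "%M", tz = "UTC")) / 60 +
    as.numeric(format(lt, "%OS", tz = "UTC")) / 3600
}

#' Split a track into diurnal and nocturnal fixes
#'
#' Diurnal fixes fall in the half-open local clock window
#' `[window[1], window[2])` at the fixed `utcOffset`; a fix at exactly the
#' window start is diurnal, one at the window end is nocturnal. The
#' partition is exhaustive and disjoint. Diurnal fixes feed the home-range
#' estimation, nocturnal fixes the roost detection.
#'
#' @param track a [VultureTrack-class] (or a fix data.frame with a
#'   `timestamp` column).
#' @param window numeric `c(start, end)` local clock hours, default
#'   `c(6, 18)`.
#' @param utcOffset fixed offset from UTC in hours (default +2).
#' @return list with data.frames `diurnal` and `nocturnal`, each with a
#'   `local_date` column added.
#' @export
splitDayNight <- function(track, window = c(6, 18), utcOffset = 2) {
  if (window[1] >= window[2]) stop("window start must be before end")
  f <- if (is(track, "VultureTrack")) track@fixes else track
  h <- localHour(f$timestamp, utcOffset)
  f$local_date <- localDate(f$timestamp, utcOffset)
  day <- h >= window[1] & h < window[2]
  list(diurnal = f[day, , drop = FALSE],
       nocturnal = f[!day, , drop = FALSE])
}

#' Season calendar
#'
#' Per-year season start dates. Defaults are the fixed civil dates of the
#' equinoxes and solstices (Mar 20, Jun 21, Sep 22, Dec 21); at daily
#' granularity the minute-level astronomical variation is irrelevant, and
#' the dates are editable per year.
#'
#' @param years integer vector of calendar years to cover.
#' @param boundaries named character vector of month-day season starts.
#' @return data.frame with columns `year`, `season`, `start`.
#' @export
seasonCalendar <- function(years,
                           boundaries = c(spring = "03-20", summer = "06-21",
                                          autumn = "09-22", winter = "12-21")) {
  stopifnot(all(c("spring", "summer", "autumn", "winter") %in%
                  names(boundaries)))
  grid <- expand.grid(year = sort(unique(years)),
                      season = c("spring", "summer", "autumn", "winter"),
                      stringsAsFactors = FALSE)
  grid$start <- as.Date(paste0(grid$year, "-", boundaries[grid$season]))
  grid <- grid[order(grid$start), ]
  if (any(diff(as.numeric(grid$start)) <= 0))
    stop("season boundaries must be strictly increasing within each year")
  rownames(grid) <- NULL
  grid
}

#' Assign dates to seasons
#'
#' A boundary date starts its season (the configured summer-solstice date
#' is the first day of summer). Winter spans the year boundary and is
#' keyed by the year of its December start.
#'
#' @param dates `Date` vector.
#' @param calendar a [seasonCalendar()]; must cover all `dates`.
#' @return data.frame with `season` and `season_year` (the year of the
#'   season instance's start) per date.
#' @export
assignSeason <- function(dates, calendar) {
  dates <- as.Date(dates)
  iv <- findInterval(as.numeric(dates), as.numeric(calendar$start))
  if (any(iv == 0) || any(dates >= max(calendar$start) + 95))
    stop("date(s) outside season calendar coverage; extend the calendar")
  data.frame(season = calendar$season[iv], season_year = calendar$year[iv])
}

#' Per-bird tracked days
#'
#' The number of distinct local dates with at least one retained diurnal
#' fix -- the "tracking days with data" notion used throughout the
#' coverage filters and the movement-day denominators.
#'
#' @inheritParams splitDayNight
#' @return integer day count.
#' @export
trackedDays <- function(track, window = c(6, 18), utcOffset = 2) {
  d <- splitDayNight(track, window, utcOffset)$diurnal
  length(unique(d$local_date))
}

#' Season coverage per bird
#'
#' Counts, for every season instance overlapped by the track, the distinct
#' local dates with at least one diurnal fix, and flags whether the
#' bird-season passes the completeness filter: seasons in which the bird
#' transmitted on fewer than `minDays` days (less than about half a
#' season) are excluded so that occasional visits are not over-weighted.
#'
#' @inheritParams splitDayNight
#' @param calendar a [seasonCalendar()]; defaults to one spanning the
#'   track (with a year of padding).
#' @param minDays minimum days-with-data per season (default 45).
#' @return data.frame with `season`, `season_year`, `start`, `end`,
#'   `season_days`, `days_with_data`, `include`.
#' @export
seasonCoverage <- function(track, calendar = NULL, window = c(6, 18),
                           utcOffset = 2, minDays = 45) {
  d <- splitDayNight(track, window, utcOffset)$diurnal
  if (!nrow(d)) {
    return(data.frame(season = character(), season_year = integer(),
                      start = as.Date(character()), end = as.Date(character()),
                      season_days = integer(), days_with_data = integer(),
                      include = logical()))
  }
  dates <- unique(d$local_date)
  if (is.null(calendar)) {
    yrs <- as.integer(format(range(dates), "%Y"))
    calendar <- seasonCalendar((yrs[1] - 1):(yrs[2] + 1))
  }
  asg <- assignSeason(dates, calendar)
  key <- paste(asg$season_year, asg$season)
  tab <- table(key)
  calKey <- paste(calendar$year, calendar$season)
  idx <- match(names(tab), calKey)
  ends <- c(calendar$start[-1] - 1, max(calendar$start) + 94)
  out <- data.frame(season = calendar$season[idx],
                    season_year = calendar$year[idx],
                    start = calendar$start[idx], end = ends[idx],
                    season_days = as.integer(ends[idx] - calendar$start[idx] + 1),
                    days_with_data = as.integer(tab))
  out$include <- seasonCoverageFilter(out$days_with_data, minDays)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

#' @rdname seasonCoverage
#' @param daysWithData integer vector of distinct days with data.
#' @return `seasonCoverageFilter`: logical, `TRUE` (include) iff
#'   `daysWithData >= minDays`.
#' @export
seasonCoverageFilter <- function(daysWithData, minDays = 45) {
  daysWithData >= minDays
}

#' Minimum-tracking filter
#'
#' Birds tracked for fewer than `minDays` days (distinct dates with
#' diurnal data after cleaning) are excluded from all further analysis.
#'
#' @inheritParams splitDayNight
#' @param minDays minimum tracked days (default 50).
#' @return logical: `TRUE` iff the track passes.
#' @export
minTrackingFilter <- function(track, minDays = 50, window = c(6, 18),
                              utcOffset = 2) {
  trackedDays(track, window, utcOffset) >= minDays
}
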