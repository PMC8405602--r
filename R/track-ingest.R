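#' Column mapping for GPS fix files
#'
#' Describes how to read a fix CSV: which columns hold the bird id,
#' timestamp and coordinates. Timestamps are expected ISO-8601 and are
#' interpreted in `tz` (the transmitters report UTC).
#'
#' @param id,timestamp,lon,lat column names in the file.
#' @param tz timestamp time zone.
#' @export
fixDialect <- function(id = "bird_id", timestamp = "timestamp",
                       lon = "lon", lat = "lat", tz = "UTC") {
  list(id = id, timestamp = timestamp, lon = lon, lat = lat, tz = tz)
}

#' Read raw GPS fixes from a CSV file
#'
#' Reads one fix per well-formed row, in file order. In lenient mode
#' (default) malformed rows (unparseable timestamp, missing or out-of-range
#' coordinates) are dropped with a warning; in strict mode they are an
#' error.
#'
#' @param path CSV file path.
#' @param dialect a [fixDialect()] column mapping.
#' @param strict error on malformed rows instead of skipping them.
#' @return data.frame with columns `bird_id`, `timestamp` (POSIXct UTC),
#'   `lon`, `lat`; attribute `nRead` holds the raw row count.
#' @export
readFixes <- function(path, dialect = fixDialect(), strict = FALSE) {
  if (!file.exists(path)) stop("fix file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- unlist(dialect[c("id", "timestamp", "lon", "lat")])
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("fix file lacks mapped column(s): ", paste(miss, collapse = ", "))
  ## parse row-by-row robustly: a malformed row must not poison the rest
  tsRaw <- as.character(raw[[dialect$timestamp]])
  ts <- as.POSIXct(rep(NA_real_, length(tsRaw)), origin = "1970-01-01",
                   tz = dialect$tz)
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(ts))
    if (!length(idx)) break
    ts[idx] <- as.POSIXct(strptime(tsRaw[idx], fmt, tz = dialect$tz))
  }
  attr(ts, "tzone") <- "UTC"
  lon <- suppressWarnings(as.numeric(raw[[dialect$lon]]))
  lat <- suppressWarnings(as.numeric(raw[[dialect$lat]]))
  ok <- !is.na(ts) & !is.na(lon) & !is.na(lat) &
    abs(lat) <= 90 & abs(lon) <= 180
  if (any(!ok)) {
    if (strict)
      stop(sum(!ok), " malformed row(s) in ", path)
    warning(sum(!ok), " malformed row(s) skipped in ", basename(path))
  }
  out <- data.frame(bird_id = as.character(raw[[dialect$id]])[ok],
                    timestamp = ts[ok], lon = lon[ok], lat = lat[ok],
                    stringsAsFactors = FALSE)
  message("readFixes: ", nrow(out), " of ", nrow(raw), " rows read from ",
          basename(path))
  attr(out, "nRead") <- nrow(raw)
  out
}

#' Read per-bird metadata
#'
#' Expects columns `bird_id`, `release_date` (ISO date, may be empty for
#' wild-caught birds), `capture_group` (`wild_caught`,
#' `wild_rehabilitated` or `reintroduced`) and `tagging_location`.
#'
#' @param path CSV file path.
#' @return data.frame of bird metadata.
#' @export
readBirdMeta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "release_date", "capture_group", "tagging_location")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  m$release_date <- as.Date(ifelse(nzchar(trimws(m$release_date)),
                                   m$release_date, NA))
  bad <- !is.na(m$capture_group) & nzchar(m$capture_group) &
    !m$capture_group %in% VALID_CAPTURE_GROUPS
  if (any(bad))
    stop("unknown capture_group: ",
         paste(unique(m$capture_group[bad]), collapse = ", "))
  m
}

#' Assemble a track from a fix table
#'
#' Sorts fixes by time (stable sort, preserving file order among equal
#' timestamps) and attaches metadata.
#'
#' @param fixes data.frame with `bird_id`, `timestamp`, `lon`, `lat`
#'   (e.g. from [readFixes()]); rows for other birds are ignored.
#' @param birdId the bird to extract; defaults to the single id present.
#' @param releaseDate `Date` or `NA`.
#' @param captureGroup one of `"wild_caught"`, `"wild_rehabilitated"`,
#'   `"reintroduced"`, or `NA`.
#' @param taggingLocation free text.
#' @return a [VultureTrack-class].
#' @export
makeTrack <- function(fixes, birdId = NULL, releaseDate = as.Date(NA),
                      captureGroup = NA_character_,
                      taggingLocation = NA_character_) {
  if (is.null(birdId)) {
    ids <- unique(fixes$bird_id)
    if (length(ids) != 1)
      stop("fixes contain ", length(ids), " bird ids; give birdId")
    birdId <- ids
  }
  f <- fixes[fixes$bird_id == birdId, , drop = FALSE]
  f <- f[order(f$timestamp), , drop = FALSE]
  f <- data.frame(timestamp = f$timestamp, lon = f$lon, lat = f$lat,
                  x = rep(NA_real_, nrow(f)), y = rep(NA_real_, nrow(f)))
  rownames(f) <- NULL
  new("VultureTrack", birdId = as.character(birdId), fixes = f,
      releaseDate = as.Date(releaseDate),
      captureGroup = as.character(captureGroup),
      taggingLocation = as.character(taggingLocation),
      projection = list())
}

#' @rdname makeTrack
#' @param meta optional metadata data.frame from [readBirdMeta()].
#' @return `makeTracks`: named list of [VultureTrack-class], one per bird
#'   id present in `fixes`.
#' @export
makeTracks <- function(fixes, meta = NULL) {
  ids <- unique(fixes$bird_id)
  out <- lapply(ids, function(id) {
    rd <- as.Date(NA); cg <- NA_character_; tl <- NA_character_
    if (!is.null(meta) && id %in% meta$bird_id) {
      r <- meta[match(id, meta$bird_id), ]
      rd <- r$release_date; cg <- r$capture_group; tl <- r$tagging_location
    }
    makeTrack(fixes, id, rd, cg, tl)
  })
  names(out) <- ids
  out
}

.replaceFixes <- function(track, f) {
  rownames(f) <- NULL
  track@fixes <- f
  track
}

#' Remove duplicate fixes
#'
#' Keeps the first record per timestamp, preserving order. Identical
#' coordinates at different times are legitimate (roosting birds) and are
#' kept.
#'
#' @param track a [VultureTrack-class] sorted by time.
#' @return the deduplicated track; attribute `nRemoved` reports the drops.
#' @export
deduplicate <- function(track) {
  stopifnot(is(track, "VultureTrack"))
  f <- track@fixes
  keep <- !duplicated(f$timestamp)
  out <- .replaceFixes(track, f[keep, , drop = FALSE])
  attr(out, "nRemoved") <- sum(!keep)
  out
}

#' Remove speed-implausible fixes
#'
#' Sequential speed filter: scanning forward, a fix is dropped when the
#' speed implied from the previous *retained* fix exceeds `maxSpeed`.
#' Distances use the projected coordinates when available, otherwise
#' great-circle (haversine) distance.
#'
#' @param track a [VultureTrack-class].
#' @param maxSpeed maximum plausible speed in km/h (default 120, above
#'   sustained vulture flight).
#' @return the filtered track; attribute `nRemoved` reports the drops.
#' @export
removeOutliers <- function(track, maxSpeed = 120) {
  stopifnot(is(track, "VultureTrack"))
  if (!is.numeric(maxSpeed) || length(maxSpeed) != 1 || maxSpeed <= 0)
    stop("maxSpeed must be a single positive number (km/h)")
  f <- track@fixes
  n <- nrow(f)
  if (n < 2) return(`attr<-`(track, "nRemoved", 0L))
  t <- as.numeric(f$timestamp)
  proj <- isProjected(track)
  vmax <- maxSpeed / 3.6  # m/s
  keep <- logical(n); keep[1] <- TRUE
  last <- 1L
  for (i in 2:n) {
    dt <- t[i] - t[last]
    if (dt <= 0) next  # duplicate-time record: drop
    d <- if (proj) {
      sqrt((f$x[i] - f$x[last])^2 + (f$y[i] - f$y[last])^2)
    } else {
      geosphere::distHaversine(c(f$lon[last], f$lat[last]),
                               c(f$lon[i], f$lat[i]))
    }
    if (d / dt <= vmax) { keep[i] <- TRUE; last <- i }
  }
  out <- .replaceFixes(track, f[keep, , drop = FALSE])
  attr(out, "nRemoved") <- sum(!keep)
  out
}

#' Drop the post-release acclimatisation period
#'
#' Retains only fixes strictly after `releaseDate + nDays` days, so the
#' first `nDays` days after release (the re-acclimatisation period of
#' released birds) are excluded. Tracks without a release date
#' (wild-caught birds) pass through unchanged.
#'
#' @param track a [VultureTrack-class].
#' @param nDays length of the acclimatisation period in days (default 50).
#' @return the filtered track.
#' @export
acclimatisationFilter <- function(track, nDays = 50) {
  stopifnot(is(track, "VultureTrack"))
  if (is.na(track@releaseDate)) return(track)
  cutoff <- as.POSIXct(paste(track@releaseDate, "00:00:00"), tz = "UTC") +
    nDays * 86400
  f <- track@fixes
  .replaceFixes(track, f[f$timestamp > cutoff, , drop = FALSE])
}

#' Restrict a track to a study region
#'
#' Keeps fixes inside or on the boundary of the region polygon (even-odd
#' rule via [pointInPolygon()]).
#'
#' @param track a [VultureTrack-class]; must be projected if the region is
#'   defined in projected coordinates.
#' @param region a [StudyRegion-class], e.g. [balkanRegion()].
#' @return the clipped track.
#' @export
clipToRegion <- function(track, region = balkanRegion()) {
  stopifnot(is(track, "VultureTrack"), is(region, "StudyRegion"))
  f <- track@fixes
  if (!nrow(f)) return(track)
  if (region@coords == "xy") {
    if (!isProjected(track))
      stop("region is in projected coordinates but track is not projected")
    keep <- pointInPolygon(f$x, f$y, region@rings)
  } else {
    keep <- pointInPolygon(f$lon, f$lat, region@rings)
  }
  .replaceFixes(track, f[keep, , drop = FALSE])
}

#' Construct a study region
#'
#' @param rings list of 2-column vertex matrices (outer ring first; holes
#'   via the even-odd rule).
#' @param name region label.
#' @param coords `"lonlat"` (degrees) or `"xy"` (projected metres).
#' @return a [StudyRegion-class].
#' @export
studyRegion <- function(rings, name = "region", coords = "lonlat") {
  if (is.matrix(rings)) rings <- list(rings)
  new("StudyRegion", name = name, rings = rings, coords = coords)
}

#' Coarse Balkan Peninsula + Eastern Alps study region
#'
#' A deliberately coarse polygon spanning the Balkan Peninsula and the
#' adjoining south-eastern Alps, used to exclude fixes from outside the
#' study system (in particular Middle-East wintering movements). Supply
#' your own [studyRegion()] for precise boundaries.
#'
#' @return a [StudyRegion-class] in lon/lat.
#' @export
balkanRegion <- function() {
  v <- matrix(c(
    12.0, 45.3,   12.3, 47.9,   15.5, 48.3,   18.5, 47.6,
    21.5, 46.9,   23.0, 45.9,   26.5, 45.8,   28.9, 45.5,
    29.4, 43.5,   28.6, 41.9,   29.5, 40.9,   26.2, 38.8,
    24.5, 34.4,   21.0, 34.6,   19.0, 39.4,   18.2, 42.4,
    13.4, 45.5), ncol = 2, byrow = TRUE)
  studyRegion(v, name = "Balkan Peninsula and Eastern Alps")
}

#' Write cleaned fixes to CSV
#'
#' @param tracks a [VultureTrack-class] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFixesCSV <- function(tracks, path) {
  if (is(tracks, "VultureTrack")) tracks <- list(tracks)
  tab <- do.call(rbind, lapply(tracks, function(tr) {
    f <- tr@fixes
    if (!nrow(f)) return(NULL)
    data.frame(bird_id = tr@birdId,
               timestamp = format(f$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               lon = f$lon, lat = f$lat, x = f$x, y = f$y)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
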