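## Daily occupancy of the zone network and roost detection.

#' Classify bird-days against the zone network
#'
#' Each bird-day with at least one diurnal fix is classified by the
#' fraction of its diurnal fixes falling inside the union of all zones:
#' `inside` when the fraction strictly exceeds `threshold` (default 0.95
#' of the day's fixes -- fixes arrive at a near-uniform 10-minute cadence,
#' so fix count stands in for time), `outside` when no fix is in any zone,
#' and `partial` otherwise. `dominant_zone` is the single zone holding the
#' most of the day's fixes (ties broken by zone id).
#'
#' @param tracks a projected [VultureTrack-class] or list of them.
#' @param zones a [VultureZoneSet-class], or a (named) list of
#'   [LatticeRegion-class] zone polygons.
#' @param threshold inside-fraction threshold (default 0.95).
#' @param window,utcOffset diurnal window, as in [splitDayNight()].
#' @return data.frame with `bird_id`, `date`, `n_fixes`, `fraction_in`,
#'   `category`, `dominant_zone`.
#' @export
classifyDays <- function(tracks, zones, threshold = 0.95,
                         window = c(6, 18), utcOffset = 2) {
  if (is(tracks, "VultureTrack")) tracks <- list(tracks)
  regs <- if (is(zones, "VultureZoneSet")) zones@regions
          else if (is(zones, "LatticeRegion")) list(Z1 = zones)
          else zones
  if (is.null(names(regs)) && length(regs))
    names(regs) <- paste0("Z", seq_along(regs))
  out <- NULL
  for (tr in tracks) {
    d <- splitDayNight(tr, window, utcOffset)$diurnal
    if (!nrow(d)) next
    inZone <- matrix(FALSE, nrow(d), length(regs))
    for (zi in seq_along(regs))
      inZone[, zi] <- latticeContains(regs[[zi]], d$x, d$y)
    anyIn <- if (length(regs)) rowSums(inZone) > 0 else rep(FALSE, nrow(d))
    for (day in split(seq_len(nrow(d)), d$local_date)) {
      nf <- length(day)
      fin <- sum(anyIn[day]) / nf
      cat_ <- if (fin > threshold) "inside"
              else if (fin == 0) "outside" else "partial"
      dom <- NA_character_
      if (fin > 0) {
        cnt <- colSums(inZone[day, , drop = FALSE])
        dom <- names(regs)[which.max(cnt)]  # which.max: first = lexicographic
      }
      out <- rbind(out, data.frame(bird_id = tr@birdId,
                                   date = d$local_date[day[1]],
                                   n_fixes = nf, fraction_in = fin,
                                   category = cat_, dominant_zone = dom))
    }
  }
  if (is.null(out))
    out <- data.frame(bird_id = character(), date = as.Date(character()),
                      n_fixes = integer(), fraction_in = numeric(),
                      category = character(), dominant_zone = character())
  rownames(out) <- NULL
  out
}

#' Round half away from zero
#'
#' Unlike [round()] (banker's rounding), 0.005 rounds up to 0.01.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise occupancy categories
#'
#' Counts and percentages (rounded half-away-from-zero to 2 decimal
#' places) of `inside` / `partial` / `outside` bird-days.
#'
#' @param classifications data.frame from [classifyDays()], or a named
#'   integer vector of category counts.
#' @return data.frame with `category`, `days`, `percent`; attribute
#'   `totalDays` holds the total.
#' @export
occupancySummary <- function(classifications) {
  lev <- c("inside", "partial", "outside")
  if (is.data.frame(classifications)) {
    if (!nrow(classifications)) stop("no classified days")
    counts <- table(factor(classifications$category, levels = lev))
  } else {
    if (!length(classifications) || sum(classifications) == 0)
      stop("no classified days")
    counts <- classifications[lev]
    counts[is.na(counts)] <- 0
  }
  counts <- as.integer(counts)
  total <- sum(counts)
  data.frame(category = lev, days = counts,
             percent = roundHalfUp(100 * counts / total, 2),
             row.names = NULL) -> out
  attr(out, "totalDays") <- total
  out
}

#' Detect roost sites from nocturnal fixes
#'
#' Each bird-night is reduced to a representative position (the
#' coordinate-wise median of that night's fixes; fixes before the diurnal
#' window start belong to the previous night). Nightly positions are
#' clustered by single linkage at `clusterRadius`; clusters used on at
#' least `minNights` nights are reported as roosts.
#'
#' @param x a [VultureTrack-class], list of them, or a data.frame of
#'   nocturnal fixes with `timestamp`, `x`, `y`.
#' @param clusterRadius single-linkage merge distance in metres
#'   (default 1000).
#' @param minNights minimum nights per reported roost (default 5).
#' @param window,utcOffset diurnal window used to pick nocturnal fixes
#'   when `x` holds tracks.
#' @return data.frame with `roost_id`, `x`, `y` (centroid), `n_nights`;
#'   attribute `nights` holds the per-night positions with their cluster.
#' @export
detectRoosts <- function(x, clusterRadius = 1000, minNights = 5,
                         window = c(6, 18), utcOffset = 2) {
  noct <- if (is.data.frame(x)) {
    x
  } else {
    if (is(x, "VultureTrack")) x <- list(x)
    do.call(rbind, lapply(x, function(tr)
      splitDayNight(tr, window, utcOffset)$nocturnal))
  }
  empty <- data.frame(roost_id = integer(), x = numeric(), y = numeric(),
                      n_nights = integer())
  if (is.null(noct) || !nrow(noct)) return(empty)
  ## night label: local date of (time - windowStart), so pre-dawn fixes
  ## join the evening before
  nd <- localDate(noct$timestamp - window[1] * 3600, utcOffset)
  nx <- tapply(noct$x, nd, median)
  ny <- tapply(noct$y, nd, median)
  pts <- cbind(as.numeric(nx), as.numeric(ny))
  cl <- if (nrow(pts) == 1) 1L
        else cutree(hclust(dist(pts), method = "single"),
                    h = clusterRadius)
  nights <- data.frame(night = names(nx), x = pts[, 1], y = pts[, 2],
                       cluster = cl, row.names = NULL)
  keep <- as.integer(names(which(table(cl) >= minNights)))
  if (!length(keep)) {
    attr(empty, "nights") <- nights
    return(empty)
  }
  out <- do.call(rbind, lapply(seq_along(keep), function(i) {
    sel <- cl == keep[i]
    data.frame(roost_id = i, x = mean(pts[sel, 1]), y = mean(pts[sel, 2]),
               n_nights = sum(sel))
  }))
  out <- out[order(-out$n_nights, out$x), ]
  out$roost_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "nights") <- nights
  out
}

#' Write roost sites as GeoJSON points
#'
#' @param roosts data.frame from [detectRoosts()].
#' @param path output file.
#' @param crs the [laeaCRS()] used for the metric coordinates.
#' @return `path`, invisibly.
#' @export
writeRoostsGeoJSON <- function(roosts, path, crs = laeaCRS()) {
  feats <- lapply(seq_len(nrow(roosts)), function(i) {
    ll <- laeaInverse(roosts$x[i], roosts$y[i], crs)
    list(type = "Feature",
         properties = list(roost_id = roosts$roost_id[i],
                           n_nights = roosts$n_nights[i]),
         geometry = list(type = "Point",
                         coordinates = c(round(ll$lon, 7),
                                         round(ll$lat, 7))))
  })
  writeLines(jsonlite::toJSON(list(type = "FeatureCollection",
                                   features = feats),
                              auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}
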