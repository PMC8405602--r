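## Vulture key zone inference.
##
## Stage 1 (spatial): dissolve all per-bird home-range isopleths and split
## the union into maximal spatially-connected patches ("candidate areas").
## Stage 2 (behavioural): merge candidate areas that some bird connects by
## frequent within-day movement -- if a bird spent more than `threshold`
## (default 5%) of its tracked days with fixes in two areas on the same
## day, the areas belong to one zone.

#' Spatially connected candidate areas
#'
#' Dissolves per-bird home ranges into maximal connected patches. Two
#' ranges belong to the same patch exactly when a chain of pairwise
#' intersecting polygons links them, so the result equals the connected
#' components of the polygon-intersection graph, dissolved.
#'
#' @param ranges list of per-bird [IsoplethSet-class] (one per bird,
#'   typically the 95% home range), or [LatticeRegion-class] objects.
#' @param minPatchKm2 drop connected patches smaller than this area
#'   (km^2); isopleths of wide-ranging birds shed small disconnected
#'   fragments along rarely-used corridors, which are discretisation
#'   noise rather than usable areas. `0` (default) keeps every patch; if
#'   the filter would drop everything the largest patch is kept.
#' @param cores optional list of per-bird core-area [IsoplethSet-class]
#'   (e.g. the 50% isopleths). When given, only patches containing at
#'   least one core cell are kept: a candidate area must host
#'   concentrated use by some bird, which screens out transit slivers in
#'   a scale-free way (every reported vulture zone has a core area).
#' @return a [CandidateAreaSet-class]; areas are ordered largest first and
#'   labelled `A1`, `A2`, ...
#' @export
spatialComponents <- function(ranges, minPatchKm2 = 0, cores = NULL) {
  if (!length(ranges)) stop("no home ranges supplied")
  regs <- .flattenRegions(ranges)
  ids <- vapply(seq_along(ranges), function(i) {
    r <- ranges[[i]]
    if (is(r, "IsoplethSet") && !is.na(r@birdId)) r@birdId
    else names(ranges)[i] %||% paste0("bird", i)
  }, character(1))
  u <- latticeUnion(regs)
  parts <- latticeParts(u)
  if (minPatchKm2 > 0) {
    big <- vapply(parts, areaKm2, numeric(1)) >= minPatchKm2
    if (!any(big)) big[1] <- TRUE  # parts are sorted largest first
    parts <- parts[big]
  }
  if (!is.null(cores)) {
    coreKeys <- unique(unlist(lapply(.flattenRegions(cores),
                                     function(r) cellKey(r@cells))))
    hasCore <- vapply(parts, function(p)
      any(cellKey(p@cells) %in% coreKeys), logical(1))
    if (!any(hasCore)) hasCore[1] <- TRUE
    parts <- parts[hasCore]
  }
  partKeys <- lapply(parts, function(p) cellKey(p@cells))
  members <- lapply(partKeys, function(pk) {
    hit <- vapply(seq_along(regs), function(i)
      any(cellKey(regs[[i]]@cells) %in% pk), logical(1))
    sort(ids[hit])
  })
  names(parts) <- paste0("A", seq_along(parts))
  names(members) <- names(parts)
  new("CandidateAreaSet", regions = parts, members = members,
      cellSize = u@cellSize)
}

#' Movement linkage between candidate areas
#'
#' A local date counts as a movement day for an (unordered) pair of areas
#' when that day's diurnal fixes include at least one fix in each. For
#' every bird and pair, the movement fraction is movement days divided by
#' the bird's total tracked days (distinct dates with diurnal data). Areas
#' are linked when any bird's fraction strictly exceeds `threshold`; zones
#' are the connected components of the linkage graph over candidate areas
#' (spatial connection is already dissolved into the candidates).
#'
#' @param tracks list of projected, cleaned [VultureTrack-class].
#' @param areas a [CandidateAreaSet-class] from [spatialComponents()].
#' @param threshold movement-day fraction above which areas merge
#'   (strict `>`; default 0.05).
#' @param window,utcOffset diurnal window, as in [splitDayNight()].
#' @return a [VultureZoneSet-class]; slot `linkage` holds the per-bird
#'   pair records (`bird_id`, `area_a`, `area_b`, `movement_days`,
#'   `tracked_days`, `fraction`).
#' @export
movementLinkage <- function(tracks, areas, threshold = 0.05,
                            window = c(6, 18), utcOffset = 2) {
  stopifnot(is(areas, "CandidateAreaSet"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  if (is(tracks, "VultureTrack")) tracks <- list(tracks)
  nA <- length(areas@regions)
  ## key -> area id lookup over all candidate cells (areas are disjoint)
  keys <- unlist(lapply(areas@regions, function(r) cellKey(r@cells)))
  owner <- rep(seq_len(nA), vapply(areas@regions, function(r)
    nrow(r@cells), integer(1)))
  cs <- areas@cellSize
  recs <- NULL
  for (tr in tracks) {
    d <- splitDayNight(tr, window, utcOffset)$diurnal
    tdays <- length(unique(d$local_date))
    if (tdays == 0) {
      warning("bird ", tr@birdId, " has no tracked days; skipped")
      next
    }
    fk <- cellKey(cbind(floor(d$x / cs), floor(d$y / cs)))
    aid <- owner[match(fk, keys)]
    byday <- split(aid, d$local_date)
    pairCount <- new.env(parent = emptyenv())
    for (day in byday) {
      present <- sort(unique(day[!is.na(day)]))
      if (length(present) < 2) next
      prs <- utils::combn(present, 2)
      for (k in seq_len(ncol(prs))) {
        key <- paste(prs[1, k], prs[2, k], sep = "-")
        pairCount[[key]] <- (pairCount[[key]] %||% 0L) + 1L
      }
    }
    for (key in ls(pairCount)) {
      ab <- as.integer(strsplit(key, "-")[[1]])
      recs <- rbind(recs, data.frame(
        bird_id = tr@birdId, area_a = names(areas@regions)[ab[1]],
        area_b = names(areas@regions)[ab[2]],
        movement_days = pairCount[[key]], tracked_days = tdays,
        fraction = pairCount[[key]] / tdays))
    }
  }
  if (is.null(recs))
    recs <- data.frame(bird_id = character(), area_a = character(),
                       area_b = character(), movement_days = integer(),
                       tracked_days = integer(), fraction = numeric())
  ## build the zone partition
  linked <- recs[recs$fraction > threshold, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nA, directed = FALSE)
  if (nrow(linked)) {
    e <- rbind(match(linked$area_a, names(areas@regions)),
               match(linked$area_b, names(areas@regions)))
    g <- igraph::add_edges(g, as.vector(e))
  }
  comp <- igraph::components(g)$membership
  zoneOf <- split(seq_len(nA), comp)
  ## deterministic order: by smallest constituent area index
  zoneOf <- zoneOf[order(vapply(zoneOf, min, integer(1)))]
  regions <- lapply(zoneOf, function(ix) latticeUnion(areas@regions[ix]))
  members <- lapply(zoneOf, function(ix)
    sort(unique(unlist(areas@members[ix]))))
  compAreas <- lapply(zoneOf, function(ix) names(areas@regions)[ix])
  ids <- paste0("Z", seq_along(zoneOf))
  names(regions) <- ids; names(members) <- ids; names(compAreas) <- ids
  new("VultureZoneSet", zoneIds = ids, regions = regions,
      members = members, componentAreas = compAreas, linkage = recs,
      cellSize = areas@cellSize)
}

#' Build zones from home ranges and tracks
#'
#' Convenience wrapper: [spatialComponents()] then [movementLinkage()].
#'
#' @inheritParams movementLinkage
#' @inheritParams spatialComponents
#' @param ranges per-bird home-range [IsoplethSet-class] list.
#' @return a [VultureZoneSet-class].
#' @export
buildZones <- function(ranges, tracks, threshold = 0.05, cores = NULL,
                       minPatchKm2 = 0, window = c(6, 18),
                       utcOffset = 2) {
  movementLinkage(tracks, spatialComponents(ranges, minPatchKm2, cores),
                  threshold, window, utcOffset)
}

#' Per-zone report: members, core areas and home ranges
#'
#' For each zone, member birds' fixes are restricted to the bird's days
#' with at least one fix inside the zone, a dBBMM utilization distribution
#' is computed per bird, and the per-bird 50% and 95% isopleths are
#' dissolved into the zone's core area and home range (set
#' `pooled = TRUE` to mix the member UDs, weighted by tracking time,
#' before taking isopleths instead).
#'
#' @param zones a [VultureZoneSet-class].
#' @param tracks named list of projected [VultureTrack-class] (names or
#'   `birdId`s must cover the zones' member birds).
#' @param levels isopleth levels, default `c(0.5, 0.95)`.
#' @param cellSize raster cell size in metres for the per-zone UDs.
#' @param pooled mix member UDs instead of dissolving member isopleths.
#' @param window,utcOffset diurnal window.
#' @param ... passed to [estimateMotionVariance()].
#' @return data.frame with one row per zone: `zone`, `n_birds`,
#'   `member_birds`, `core50_km2`, `homerange95_km2` (column names track
#'   `levels`).
#' @export
zoneReport <- function(zones, tracks, levels = c(0.5, 0.95),
                       cellSize = 500, pooled = FALSE,
                       window = c(6, 18), utcOffset = 2, ...) {
  stopifnot(is(zones, "VultureZoneSet"))
  if (is(tracks, "VultureTrack")) tracks <- list(tracks)
  ids <- vapply(tracks, birdId, character(1))
  names(tracks) <- ids
  rows <- NULL
  for (zi in seq_along(zones@zoneIds)) {
    zreg <- zones@regions[[zi]]
    mem <- zones@members[[zi]]
    uds <- list(); wts <- numeric()
    for (b in mem) {
      tr <- tracks[[b]]
      if (is.null(tr)) next
      d <- splitDayNight(tr, window, utcOffset)$diurnal
      if (!nrow(d)) next
      inz <- latticeContains(zreg, d$x, d$y)
      zdays <- unique(d$local_date[inz])
      sub <- d[d$local_date %in% zdays, , drop = FALSE]
      if (nrow(sub) < 2) next
      trz <- tr
      trz@fixes <- data.frame(timestamp = sub$timestamp, lon = sub$lon,
                              lat = sub$lat, x = sub$x, y = sub$y)
      mvs <- tryCatch(estimateMotionVariance(trz, ...),
                      error = function(e)
                        estimateMotionVariance(trz, static = TRUE, ...))
      uds[[b]] <- computeUD(trz, mvs, cellSize = cellSize)
      wts[b] <- as.numeric(difftime(max(sub$timestamp), min(sub$timestamp),
                                    units = "secs"))
    }
    areas <- setNames(rep(NA_real_, length(levels)),
                      paste0("level", levels * 100))
    if (length(uds)) {
      for (li in seq_along(levels)) {
        lv <- levels[li]
        if (pooled) {
          pud <- .mixUDs(uds, wts / sum(wts))
          areas[li] <- areaKm2(isopleth(pud, lv))
        } else {
          iso <- lapply(uds, isopleth, level = lv)
          areas[li] <- areaKm2(latticeUnion(iso))
        }
      }
    }
    row <- data.frame(zone = zones@zoneIds[zi], n_birds = length(mem),
                      member_birds = paste(mem, collapse = ";"))
    for (li in seq_along(levels))
      row[[sprintf("area%d_km2", round(levels[li] * 100))]] <- areas[li]
    rows <- rbind(rows, row)
  }
  if (is.null(rows))
    rows <- data.frame(zone = character(), n_birds = integer(),
                       member_birds = character())
  rownames(rows) <- NULL
  rows
}

## weight-mix UD rasters defined on (possibly different) grids sharing a
## lattice; result lives on the bounding grid
.mixUDs <- function(uds, w) {
  cs <- uds[[1]]@grid@cellSize
  gx <- range(unlist(lapply(uds, function(u)
    c(u@grid@x0, u@grid@x0 + u@grid@nCols * cs))))
  gy <- range(unlist(lapply(uds, function(u)
    c(u@grid@y0, u@grid@y0 + u@grid@nRows * cs))))
  grid <- new("GridSpec", x0 = gx[1], y0 = gy[1], cellSize = cs,
              nCols = as.integer(round((gx[2] - gx[1]) / cs)),
              nRows = as.integer(round((gy[2] - gy[1]) / cs)))
  W <- matrix(0, grid@nRows, grid@nCols)
  for (i in seq_along(uds)) {
    u <- uds[[i]]
    ri <- as.integer(round((u@grid@y0 - grid@y0) / cs))
    ci <- as.integer(round((u@grid@x0 - grid@x0) / cs))
    W[ri + seq_len(u@grid@nRows), ci + seq_len(u@grid@nCols)] <-
      W[ri + seq_len(u@grid@nRows), ci + seq_len(u@grid@nCols)] +
      w[i] * u@weights
  }
  new("UDRaster", grid = grid, weights = W / sum(W),
      projection = uds[[1]]@projection)
}
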