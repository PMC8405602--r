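## Central S4 containers. All spatial coordinates are either geographic
## (lon/lat, WGS84 degrees) or metres in a local equal-area projection (see
## laeaCRS()). Lattice-based polygon containers index an absolute square
## lattice (cell i covers [i*cellSize, (i+1)*cellSize)), so regions computed
## for different birds on grids with the same cell size are directly
## comparable with exact set operations.

VALID_CAPTURE_GROUPS <- c("wild_caught", "wild_rehabilitated", "reintroduced")

#' Regular raster grid specification
#'
#' Lower-left origin (`x0`, `y0`) in metres, square cells of `cellSize`
#' metres, `nCols` x `nRows` cells. Origins produced by [makeGrid()] are
#' snapped to multiples of `cellSize` so that all grids share one absolute
#' lattice.
#'
#' @slot x0,y0 numeric, lower-left corner (metres).
#' @slot cellSize numeric, cell edge length (metres), > 0.
#' @slot nCols,nRows integer grid dimensions.
#' @export
setClass("GridSpec",
  slots = c(x0 = "numeric", y0 = "numeric", cellSize = "numeric",
            nCols = "integer", nRows = "integer"))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (object@nCols < 1L || object@nRows < 1L)
    msg <- c(msg, "grid must have at least one cell")
  if (length(msg)) msg else TRUE
})

#' A per-bird GPS track
#'
#' Time-ordered GPS fixes plus bird metadata. The fix table always has
#' columns `timestamp` (POSIXct, UTC), `lon`, `lat` (WGS84 degrees) and
#' `x`, `y` (metres; `NA` until [projectTrack()] has been applied).
#'
#' @slot birdId single character identifier.
#' @slot fixes data.frame of fixes sorted by time.
#' @slot releaseDate `Date` of release into the wild, or `NA` for
#'   wild-caught birds that were never held.
#' @slot captureGroup one of `"wild_caught"`, `"wild_rehabilitated"`,
#'   `"reintroduced"`, or `NA`.
#' @slot taggingLocation free-text tagging site.
#' @slot projection empty list while unprojected, otherwise the `laeaCRS()`
#'   parameter list used to fill `x`/`y`.
#' @export
setClass("VultureTrack",
  slots = c(birdId = "character", fixes = "data.frame",
            releaseDate = "Date", captureGroup = "character",
            taggingLocation = "character", projection = "list"))

setValidity("VultureTrack", function(object) {
  msg <- character()
  f <- object@fixes
  need <- c("timestamp", "lon", "lat", "x", "y")
  if (!all(need %in% names(f)))
    return(paste("fixes must have columns", paste(need, collapse = ", ")))
  if (length(object@birdId) != 1 || is.na(object@birdId) ||
      !nzchar(object@birdId))
    msg <- c(msg, "birdId must be a single non-empty string")
  if (nrow(f)) {
    if (any(is.na(f$timestamp)))
      msg <- c(msg, "timestamps must not be NA")
    else if (is.unsorted(as.numeric(f$timestamp)))
      msg <- c(msg, "fixes must be sorted by time")
    ok <- !is.na(f$lat) & !is.na(f$lon)
    if (!all(ok) || any(abs(f$lat) > 90) || any(abs(f$lon) > 180))
      msg <- c(msg, "lon/lat must be valid WGS84 degrees")
  }
  if (!is.na(object@captureGroup) &&
      !object@captureGroup %in% VALID_CAPTURE_GROUPS)
    msg <- c(msg, paste("captureGroup must be one of",
                        paste(VALID_CAPTURE_GROUPS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Study region polygon
#'
#' A multi-ring polygon used to restrict fixes to the study area. Rings are
#' two-column matrices of vertices; even-odd filling, so interior rings act
#' as holes. `coords` records whether vertices are `"lonlat"` degrees or
#' projected `"xy"` metres.
#'
#' @export
setClass("StudyRegion",
  slots = c(name = "character", rings = "list", coords = "character"))

setValidity("StudyRegion", function(object) {
  if (!length(object@rings)) return("region must have at least one ring")
  for (r in object@rings) {
    if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3)
      return("each ring must be a 2-column matrix with >= 3 vertices")
  }
  if (!object@coords %in% c("lonlat", "xy"))
    return("coords must be 'lonlat' or 'xy'")
  if (abs(shoelaceArea(object@rings[[1]])) <= 0)
    return("outer ring must have nonzero area")
  TRUE
})

#' Windowed dBBMM motion variance series
#'
#' One Brownian motion variance (m^2/s) per inter-fix segment, estimated by
#' the sliding-window behavioural-change procedure of
#' [estimateMotionVariance()].
#'
#' @slot sigma2 numeric vector, length `nFixes - 1`, all `>= 0`.
#' @slot segStart,segEnd POSIXct segment endpoints.
#' @slot windowSize,margin integers used in estimation.
#' @slot locError assumed GPS error standard deviation (metres, per axis).
#' @export
setClass("MotionVariance",
  slots = c(birdId = "character", sigma2 = "numeric",
            segStart = "POSIXct", segEnd = "POSIXct",
            windowSize = "integer", margin = "integer",
            locError = "numeric"))

setValidity("MotionVariance", function(object) {
  msg <- character()
  if (any(!is.finite(object@sigma2)) || any(object@sigma2 < 0))
    msg <- c(msg, "sigma2 must be finite and >= 0")
  if (length(object@sigma2) != length(object@segStart) ||
      length(object@sigma2) != length(object@segEnd))
    msg <- c(msg, "sigma2/segStart/segEnd lengths differ")
  if (object@locError < 0) msg <- c(msg, "locError must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Gridded utilization distribution
#'
#' Nonnegative cell weights on a [GridSpec-class] grid, summing to 1.
#' Row 1 of `weights` is the bottom (south) row.
#'
#' @export
setClass("UDRaster",
  slots = c(grid = "GridSpec", weights = "matrix", projection = "list"))

setValidity("UDRaster", function(object) {
  w <- object@weights
  if (nrow(w) != object@grid@nRows || ncol(w) != object@grid@nCols)
    return("weights dimensions do not match grid")
  if (any(w < 0)) return("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1 (within 1e-9)")
  TRUE
})

#' Lattice-cell polygon region
#'
#' A multi-part polygon represented as a set of absolute lattice cells:
#' `cells` is a two-column integer matrix of (ix, iy) indices; cell (i, j)
#' covers `[i*cellSize, (i+1)*cellSize) x [j*cellSize, (j+1)*cellSize)`
#' metres. Union, intersection, area and point membership are exact set
#' operations; see [latticeUnion()], [latticeIntersect()],
#' [latticeContains()] and [areaKm2()].
#'
#' @export
setClass("LatticeRegion",
  slots = c(cellSize = "numeric", cells = "matrix"))

setValidity("LatticeRegion", function(object) {
  if (length(object@cellSize) != 1 || object@cellSize <= 0)
    return("cellSize must be a single positive number")
  if (ncol(object@cells) != 2) return("cells must be a 2-column matrix")
  if (nrow(object@cells) && anyDuplicated(cellKey(object@cells, object@cellSize)))
    return("cells must be unique")
  TRUE
})

#' Isopleth polygon set
#'
#' The smallest set of UD cells whose cumulative weight reaches `level`
#' (ties broken row-major), dissolved into a [LatticeRegion-class].
#'
#' @slot level fraction in (0, 1].
#' @slot region the selected cells.
#' @slot birdId,season optional provenance labels.
#' @export
setClass("IsoplethSet",
  slots = c(level = "numeric", region = "LatticeRegion",
            birdId = "character", season = "character"))

setValidity("IsoplethSet", function(object) {
  if (length(object@level) != 1 || object@level <= 0 || object@level > 1)
    return("level must be in (0, 1]")
  TRUE
})

#' Candidate areas: spatially connected home-range patches
#'
#' Output of [spatialComponents()]: each element of `regions` is one
#' maximal spatially-connected patch of the dissolved union of per-bird
#' home ranges; `members[[i]]` are the ids of birds whose home range
#' intersects patch `i`.
#'
#' @export
setClass("CandidateAreaSet",
  slots = c(regions = "list", members = "list", cellSize = "numeric"))

#' Vulture key zone set
#'
#' Final zone partition from [movementLinkage()]: candidate areas merged
#' when some bird spends more than the threshold fraction of its tracked
#' days moving among them within single days.
#'
#' @slot zoneIds zone identifiers, `"Z1"`, `"Z2"`, ...
#' @slot regions one dissolved [LatticeRegion-class] per zone.
#' @slot members character vector of bird ids per zone.
#' @slot componentAreas indices of the candidate areas merged into each zone.
#' @slot linkage the per-bird, per-area-pair movement-day records.
#' @export
setClass("VultureZoneSet",
  slots = c(zoneIds = "character", regions = "list", members = "list",
            componentAreas = "list", linkage = "data.frame",
            cellSize = "numeric"))

#' One-way ANOVA result with Fisher's LSD post-hoc
#'
#' @slot F the F statistic (`MS_between / MS_within`).
#' @slot dfBetween,dfWithin degrees of freedom.
#' @slot p upper-tail p-value from the F distribution.
#' @slot posthoc data.frame of pairwise LSD comparisons (difference in
#'   means, t statistic, p-value from pooled within-group variance).
#' @slot note diagnostic flag, e.g. degenerate zero-variance input.
#' @export
setClass("AnovaResult",
  slots = c(F = "numeric", dfBetween = "integer", dfWithin = "integer",
            p = "numeric", posthoc = "data.frame", note = "character"))

## ---- show methods -------------------------------------------------------

setMethod("show", "VultureTrack", function(object) {
  f <- object@fixes
  cat("VultureTrack '", object@birdId, "' (",
      if (is.na(object@captureGroup)) "group unknown" else object@captureGroup,
      ")\n", sep = "")
  cat("  ", nrow(f), " fixes", sep = "")
  if (nrow(f))
    cat(", ", format(min(f$timestamp), "%Y-%m-%d"), " to ",
        format(max(f$timestamp), "%Y-%m-%d"), sep = "")
  cat("; projected:", if (length(object@projection)) "yes" else "no", "\n")
})

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec: ", object@nCols, " x ", object@nRows, " cells of ",
      object@cellSize, " m, origin (", round(object@x0), ", ",
      round(object@y0), ")\n", sep = "")
})

setMethod("show", "UDRaster", function(object) {
  cat("UDRaster on ", object@grid@nCols, " x ", object@grid@nRows,
      " grid (", object@grid@cellSize, " m cells); total mass ",
      format(sum(object@weights)), "\n", sep = "")
})

setMethod("show", "MotionVariance", function(object) {
  cat("MotionVariance for '", object@birdId, "': ",
      length(object@sigma2), " segments, median ",
      format(median(object@sigma2), digits = 4), " m^2/s (w = ",
      object@windowSize, ", margin = ", object@margin, ", locError = ",
      object@locError, " m)\n", sep = "")
})

setMethod("show", "IsoplethSet", function(object) {
  cat("IsoplethSet level ", object@level * 100, "%: ",
      nrow(object@region@cells), " cells, ",
      format(areaKm2(object@region), digits = 6), " km^2\n", sep = "")
})

setMethod("show", "LatticeRegion", function(object) {
  cat("LatticeRegion: ", nrow(object@cells), " cells of ",
      object@cellSize, " m (", format(areaKm2(object), digits = 6),
      " km^2)\n", sep = "")
})

setMethod("show", "CandidateAreaSet", function(object) {
  cat("CandidateAreaSet:", length(object@regions), "spatially connected",
      "area(s)\n")
})

setMethod("show", "VultureZoneSet", function(object) {
  cat("VultureZoneSet:", length(object@zoneIds), "zone(s)\n")
  for (i in seq_along(object@zoneIds))
    cat("  ", object@zoneIds[i], ": ",
        format(areaKm2(object@regions[[i]]), digits = 6), " km^2, ",
        length(object@members[[i]]), " bird(s)\n", sep = "")
})

setMethod("show", "AnovaResult", function(object) {
  cat("One-way ANOVA: F(", object@dfBetween, ", ", object@dfWithin,
      ") = ", format(object@F, digits = 4), ", p = ",
      format(object@p, digits = 3), "\n", sep = "")
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
  if (nrow(object@posthoc)) {
    cat("  Fisher's LSD pairwise comparisons:\n")
    print(object@posthoc, row.names = FALSE)
  }
})

## ---- accessors ----------------------------------------------------------

#' @rdname VultureTrack-class
#' @param object,x a `VultureTrack`.
#' @export
setGeneric("birdId", function(object) standardGeneric("birdId"))

#' @rdname VultureTrack-class
#' @export
setMethod("birdId", "VultureTrack", function(object) object@birdId)

#' @rdname VultureTrack-class
#' @export
setGeneric("fixTable", function(object) standardGeneric("fixTable"))

#' @rdname VultureTrack-class
#' @export
setMethod("fixTable", "VultureTrack", function(object) object@fixes)

#' @rdname VultureTrack-class
#' @export
setGeneric("nFixes", function(object) standardGeneric("nFixes"))

#' @rdname VultureTrack-class
#' @export
setMethod("nFixes", "VultureTrack", function(object) nrow(object@fixes))

#' @rdname VultureTrack-class
#' @export
setGeneric("isProjected", function(object) standardGeneric("isProjected"))

#' @rdname VultureTrack-class
#' @export
setMethod("isProjected", "VultureTrack",
          function(object) length(object@projection) > 0)

#' @rdname MotionVariance-class
#' @param object a `MotionVariance`.
#' @export
setGeneric("sigma2", function(object) standardGeneric("sigma2"))

#' @rdname MotionVariance-class
#' @export
setMethod("sigma2", "MotionVariance", function(object) object@sigma2)

#' @rdname UDRaster-class
#' @param object a `UDRaster`.
#' @export
setGeneric("udWeights", function(object) standardGeneric("udWeights"))

#' @rdname UDRaster-class
#' @export
setMethod("udWeights", "UDRaster", function(object) object@weights)

#' @rdname UDRaster-class
#' @export
setGeneric("gridSpec", function(object) standardGeneric("gridSpec"))

#' @rdname UDRaster-class
#' @export
setMethod("gridSpec", "UDRaster", function(object) object@grid)

#' @rdname IsoplethSet-class
#' @param object an `IsoplethSet`.
#' @export
setGeneric("isoLevel", function(object) standardGeneric("isoLevel"))

#' @rdname IsoplethSet-class
#' @export
setMethod("isoLevel", "IsoplethSet", function(object) object@level)

#' @rdname IsoplethSet-class
#' @export
setGeneric("isoRegion", function(object) standardGeneric("isoRegion"))

#' @rdname IsoplethSet-class
#' @export
setMethod("isoRegion", "IsoplethSet", function(object) object@region)

#' @rdname VultureZoneSet-class
#' @param object a `VultureZoneSet` (or `CandidateAreaSet` for `members`).
#' @export
setGeneric("zoneIds", function(object) standardGeneric("zoneIds"))

#' @rdname VultureZoneSet-class
#' @export
setMethod("zoneIds", "VultureZoneSet", function(object) object@zoneIds)

#' @rdname VultureZoneSet-class
#' @export
setGeneric("zoneMembers", function(object) standardGeneric("zoneMembers"))

#' @rdname VultureZoneSet-class
#' @export
setMethod("zoneMembers", "VultureZoneSet", function(object) object@members)

#' @rdname VultureZoneSet-class
#' @export
setMethod("zoneMembers", "CandidateAreaSet", function(object) object@members)

#' @rdname VultureZoneSet-class
#' @export
setGeneric("zoneRegions", function(object) standardGeneric("zoneRegions"))

#' @rdname VultureZoneSet-class
#' @export
setMethod("zoneRegions", "VultureZoneSet", function(object) object@regions)

#' @rdname VultureZoneSet-class
#' @export
setMethod("zoneRegions", "CandidateAreaSet", function(object) object@regions)
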