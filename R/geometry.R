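## Lattice polygon algebra. A LatticeRegion indexes an absolute square
## lattice shared by all grids of equal cell size (makeGrid() snaps origins
## to lattice multiples), so union/intersection/area/membership are exact
## integer set operations -- no boolean polygon clipping is needed and all
## results are deterministic.

## encode (ix, iy) integer pairs as one double; exact for |i| < 2^20
KEY_OFF <- 2^20
KEY_MOD <- 2^21
cellKey <- function(cells, cellSize = NULL) {
  (cells[, 1] + KEY_OFF) * KEY_MOD + (cells[, 2] + KEY_OFF)
}
keyCells <- function(keys) {
  ix <- floor(keys / KEY_MOD) - KEY_OFF
  iy <- keys %% KEY_MOD - KEY_OFF
  cbind(ix, iy)
}

## signed polygon ring area (shoelace); vertices need not be closed
shoelaceArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Deterministic ray-casting point-in-polygon test over a list of rings.
#' Points exactly on a ring edge count as inside.
#'
#' @param px,py point coordinates (vectorised).
#' @param rings list of 2-column vertex matrices; with the even-odd rule
#'   interior rings act as holes.
#' @return logical vector.
#' @export
pointInPolygon <- function(px, py, rings) {
  n <- length(px)
  inside <- logical(n)
  onEdge <- logical(n)
  for (ring in rings) {
    xs <- ring[, 1]; ys <- ring[, 2]
    m <- nrow(ring)
    eps <- 1e-12 * max(1, max(abs(xs)), max(abs(ys)))
    for (k in seq_len(m)) {
      x1 <- xs[k]; y1 <- ys[k]
      kk <- if (k == m) 1L else k + 1L
      x2 <- xs[kk]; y2 <- ys[kk]
      ## boundary: point on segment
      cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
      seg <- abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
        px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
        py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
      onEdge <- onEdge | seg
      ## even-odd crossing of the upward ray
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
      inside <- xor(inside, crosses & !is.na(crosses))
    }
  }
  inside | onEdge
}

#' Construct a lattice region
#'
#' @param cells 2-column integer matrix of absolute lattice indices.
#' @param cellSize cell edge in metres.
#' @return a [LatticeRegion-class].
#' @export
latticeRegion <- function(cells, cellSize) {
  cells <- unique(matrix(as.integer(round(cells)), ncol = 2,
                         dimnames = NULL))
  new("LatticeRegion", cellSize = cellSize, cells = cells)
}

#' Lattice region set operations
#'
#' Exact union / intersection / difference of [LatticeRegion-class]
#' objects sharing one cell size, and point membership. These back the
#' polygon merging ("The total home range was estimated merging all the
#' annual home ranges"), seasonal overlap, zone dissolving and the per-day
#' occupancy tests.
#'
#' @param ... lattice regions (or a single list of them).
#' @return a [LatticeRegion-class].
#' @export
latticeUnion <- function(...) {
  regs <- .flattenRegions(list(...))
  cs <- .commonCellSize(regs)
  cells <- do.call(rbind, lapply(regs, function(r) r@cells))
  latticeRegion(unique(cells), cs)
}

#' @rdname latticeUnion
#' @export
latticeIntersect <- function(...) {
  regs <- .flattenRegions(list(...))
  cs <- .commonCellSize(regs)
  keys <- lapply(regs, function(r) cellKey(r@cells))
  common <- Reduce(intersect, keys)
  latticeRegion(keyCells(common), cs)
}

.flattenRegions <- function(lst) {
  out <- list()
  for (el in lst) {
    if (is(el, "LatticeRegion")) out <- c(out, el)
    else if (is(el, "IsoplethSet")) out <- c(out, el@region)
    else if (is.list(el)) out <- c(out, .flattenRegions(el))
    else stop("not a LatticeRegion")
  }
  if (!length(out)) stop("no regions supplied")
  out
}

.commonCellSize <- function(regs) {
  cs <- vapply(regs, function(r) r@cellSize, numeric(1))
  if (max(cs) - min(cs) > 1e-9) stop("regions have different cell sizes")
  cs[1]
}

#' @rdname latticeUnion
#' @param region a [LatticeRegion-class].
#' @param x,y point coordinates in metres.
#' @return `latticeContains`: logical vector, `TRUE` where the point falls
#'   in a cell of the region.
#' @export
latticeContains <- function(region, x, y) {
  cs <- region@cellSize
  pts <- cbind(floor(x / cs), floor(y / cs))
  keys <- cellKey(pts)
  keys %in% cellKey(region@cells)
}

#' Polygon area in square kilometres
#'
#' For lattice-backed regions the area is the exact cell count times the
#' cell area; additive over disjoint parts by construction.
#'
#' @param polygons a [LatticeRegion-class], [IsoplethSet-class], or a list
#'   of 2-column vertex matrices (rings; summed absolute shoelace areas).
#' @return area in km^2.
#' @export
setGeneric("areaKm2", function(polygons) standardGeneric("areaKm2"))

#' @rdname areaKm2
#' @export
setMethod("areaKm2", "LatticeRegion", function(polygons) {
  nrow(polygons@cells) * polygons@cellSize^2 / 1e6
})

#' @rdname areaKm2
#' @export
setMethod("areaKm2", "IsoplethSet", function(polygons) {
  areaKm2(polygons@region)
})

#' @rdname areaKm2
#' @export
setMethod("areaKm2", "list", function(polygons) {
  sum(vapply(polygons, function(r) abs(shoelaceArea(r)), numeric(1))) / 1e6
})

#' Spatially connected parts of a lattice region
#'
#' Splits a region into maximal connected components under 8-neighbour
#' (queen) adjacency; cells touching only at a corner still intersect as
#' closed squares, hence count as connected.
#'
#' @param region a [LatticeRegion-class].
#' @return list of [LatticeRegion-class] parts, ordered by decreasing cell
#'   count (ties: smallest cell key first).
#' @export
latticeParts <- function(region) {
  cells <- region@cells
  n <- nrow(cells)
  if (n == 0) return(list())
  keys <- cellKey(cells)
  idx <- seq_len(n)
  off <- expand.grid(dx = -1:1, dy = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0), ]
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    nb <- cbind(cells[, 1] + off$dx[k], cells[, 2] + off$dy[k])
    hit <- match(cellKey(nb), keys)
    sel <- !is.na(hit)
    if (any(sel)) edges <- rbind(edges, cbind(idx[sel], hit[sel]))
  }
  if (is.null(edges)) {
    comp <- idx  # all isolated
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_len(n)]
  }
  parts <- split(seq_len(n), comp)
  ord <- order(-vapply(parts, length, integer(1)),
               vapply(parts, function(i) min(keys[i]), numeric(1)))
  lapply(parts[ord], function(i)
    latticeRegion(cells[i, , drop = FALSE], region@cellSize))
}

#' Disc-shaped lattice region
#'
#' Cells whose centre lies within `radius` of (`cx`, `cy`). Convenience
#' constructor for tests and for rasterising the synthetic generator's
#' true zone discs.
#'
#' @param cx,cy centre (metres); `radius` in metres; `cellSize` in metres.
#' @export
latticeDisc <- function(cx, cy, radius, cellSize) {
  i0 <- floor((cx - radius) / cellSize); i1 <- floor((cx + radius) / cellSize)
  j0 <- floor((cy - radius) / cellSize); j1 <- floor((cy + radius) / cellSize)
  g <- expand.grid(ix = i0:i1, iy = j0:j1)
  ctr <- cbind((g$ix + 0.5) * cellSize, (g$iy + 0.5) * cellSize)
  keep <- (ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2 <= radius^2
  latticeRegion(as.matrix(g[keep, ]), cellSize)
}

## merge the cells of a region into maximal horizontal run rectangles,
## returned as a data.frame (x0, x1, y0, y1) in metres
regionRectangles <- function(region) {
  cells <- region@cells
  cs <- region@cellSize
  if (!nrow(cells)) {
    return(data.frame(x0 = numeric(), x1 = numeric(),
                      y0 = numeric(), y1 = numeric()))
  }
  out <- lapply(split(cells[, 1], cells[, 2]), sort)
  res <- NULL
  for (iy in names(out)) {
    xs <- out[[iy]]
    brk <- c(0, which(diff(xs) > 1), length(xs))
    for (k in seq_len(length(brk) - 1)) {
      run <- xs[(brk[k] + 1):brk[k + 1]]
      res <- rbind(res, c(min(run), max(run) + 1, as.numeric(iy),
                          as.numeric(iy) + 1))
    }
  }
  data.frame(x0 = res[, 1] * cs, x1 = res[, 2] * cs,
             y0 = res[, 3] * cs, y1 = res[, 4] * cs)
}

#' Write lattice regions as GeoJSON
#'
#' Each region becomes one MultiPolygon feature of dissolved horizontal-run
#' rectangles; coordinates are inverse-projected to WGS84 lon/lat.
#'
#' @param regions named list of [LatticeRegion-class].
#' @param path output file.
#' @param crs the [laeaCRS()] the regions' metric coordinates live in.
#' @param properties optional data.frame of per-feature properties.
#' @return `path`, invisibly.
#' @export
writeRegionGeoJSON <- function(regions, path, crs = laeaCRS(),
                               properties = NULL) {
  feats <- lapply(seq_along(regions), function(i) {
    rect <- regionRectangles(regions[[i]])
    polys <- lapply(seq_len(nrow(rect)), function(k) {
      xs <- c(rect$x0[k], rect$x1[k], rect$x1[k], rect$x0[k], rect$x0[k])
      ys <- c(rect$y0[k], rect$y0[k], rect$y1[k], rect$y1[k], rect$y0[k])
      ll <- laeaInverse(xs, ys, crs)
      list(lapply(seq_along(xs), function(j)
        c(round(ll$lon[j], 7), round(ll$lat[j], 7))))
    })
    props <- list(name = names(regions)[i] %||% paste0("region_", i),
                  area_km2 = areaKm2(regions[[i]]))
    if (!is.null(properties))
      props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a UD raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS tools.
#'
#' @param ud a [UDRaster-class].
#' @param path output `.asc` file.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(ud, path) {
  g <- ud@grid
  hdr <- c(paste("ncols", g@nCols), paste("nrows", g@nRows),
           paste("xllcorner", g@x0), paste("yllcorner", g@y0),
           paste("cellsize", g@cellSize), "NODATA_value -9999")
  ## ASCII grids are written top row first
  rows <- apply(ud@weights[rev(seq_len(g@nRows)), , drop = FALSE], 1,
                function(r) paste(format(r, digits = 10), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
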