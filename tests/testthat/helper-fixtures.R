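# Shared fixture builders. Everything is generated in code; no binary data.

# A projected track from explicit metric coordinates and fix times.
mkProjTrack <- function(x, y, times = NULL, id = "t1", crs = laeaCRS(),
                        releaseDate = as.Date(NA),
                        captureGroup = NA_character_) {
  n <- length(x)
  if (is.null(times))
    times <- as.POSIXct("2020-06-01 04:00:00", tz = "UTC") + (0:(n - 1)) * 600
  ll <- laeaInverse(x, y, crs)
  f <- data.frame(timestamp = times, lon = ll$lon, lat = ll$lat,
                  x = x, y = y)
  new("VultureTrack", birdId = id, fixes = f, releaseDate = releaseDate,
      captureGroup = captureGroup, taggingLocation = NA_character_,
      projection = unclass(crs))
}

# An unprojected track from lon/lat.
mkLonLatTrack <- function(lon, lat, times = NULL, id = "t1", ...) {
  n <- length(lon)
  if (is.null(times))
    times <- as.POSIXct("2020-06-01 04:00:00", tz = "UTC") + (0:(n - 1)) * 600
  makeTrack(data.frame(bird_id = rep(id, n), timestamp = times,
                       lon = lon, lat = lat), id, ...)
}

# Fix timestamps at given local clock hours (UTC+2 by default).
atLocalHours <- function(dates, hours, utcOffset = 2) {
  as.POSIXct(paste(dates, "00:00:00"), tz = "UTC") + hours * 3600 -
    utcOffset * 3600
}

# A UDRaster holding a discretised isotropic Gaussian.
gaussianUD <- function(sigma = 1000, cellSize = 100, extent = 6 * sigma,
                       cx = 0, cy = 0) {
  n <- as.integer(ceiling(2 * extent / cellSize))
  x0 <- floor((cx - extent) / cellSize) * cellSize
  y0 <- floor((cy - extent) / cellSize) * cellSize
  grid <- new("GridSpec", x0 = x0, y0 = y0, cellSize = cellSize,
              nCols = n, nRows = n)
  xe <- x0 + (0:n) * cellSize
  ye <- y0 + (0:n) * cellSize
  px <- diff(pnorm(xe, cx, sigma))
  py <- diff(pnorm(ye, cy, sigma))
  W <- outer(py, px)
  new("UDRaster", grid = grid, weights = W / sum(W), projection = list())
}

# Uniform UD over an nCells x nCells block.
uniformUD <- function(nCells = 10, cellSize = 100) {
  grid <- new("GridSpec", x0 = 0, y0 = 0, cellSize = cellSize,
              nCols = as.integer(nCells), nRows = as.integer(nCells))
  W <- matrix(1 / nCells^2, nCells, nCells)
  new("UDRaster", grid = grid, weights = W, projection = list())
}

# Independent union-find over a pairwise adjacency matrix (oracle for
# graph-component code paths).
unionFindMembership <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) if (adj[i, j]) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

unionFindComponents <- function(adj) {
  length(unique(unionFindMembership(adj)))
}

cellsOf <- function(x) {
  r <- if (is(x, "IsoplethSet")) x@region else x
  r@cells
}

keysOf <- function(x) griffonRanges:::cellKey(cellsOf(x))
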