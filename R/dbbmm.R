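## Dynamic Brownian bridge movement model (dBBMM).
##
## Between consecutive fixes the animal is modelled as a Brownian bridge
## with motion variance sigma^2_m (m^2/s): at time fraction alpha of a
## segment of duration T the position is Gaussian with mean the linear
## interpolation of the endpoints and per-axis variance
##
##     T * alpha * (1 - alpha) * sigma2_m
##       + (1 - alpha)^2 * delta1^2 + alpha^2 * delta2^2,
##
## where delta are the GPS error SDs of the endpoints. The "dynamic" part
## estimates sigma2_m locally in time with a sliding window and a
## behavioural-breakpoint comparison, so commuting and resident phases get
## different variances.

.bridgePrecomp <- function(x, y, t, delta) {
  n <- length(x)
  i <- 2:(n - 1)
  Tt <- t[i + 1] - t[i - 1]
  al <- (t[i] - t[i - 1]) / Tt
  mx <- (1 - al) * x[i - 1] + al * x[i + 1]
  my <- (1 - al) * y[i - 1] + al * y[i + 1]
  a <- rep(NA_real_, n); b <- a; d2 <- a
  a[i] <- Tt * al * (1 - al)
  b[i] <- ((1 - al)^2 + al^2) * delta^2
  d2[i] <- (x[i] - mx)^2 + (y[i] - my)^2
  list(a = a, b = b, d2 = d2)
}

## negative log-likelihood (2-D, additive constant dropped) of the scored
## fixes idx under motion variance s2
.bridgeNll <- function(s2, pc, idx) {
  v <- pc$a[idx] * s2 + pc$b[idx]
  sum(log(v) + pc$d2[idx] / (2 * v))
}

.fitSigma2 <- function(pc, idx) {
  if (max(pc$d2[idx]) <= 1e-12 && max(pc$b[idx]) <= 0)
    return(list(minimum = 0, objective = -Inf))  # exact stationary MLE
  up <- max(pc$d2[idx] / pc$a[idx], 1e-8) * 2 + 1e-8
  o <- optimize(.bridgeNll, c(0, up), pc = pc, idx = idx)
  ## the optimum can sit at the 0 boundary; optimize never evaluates the
  ## endpoints, so check 0 explicitly (only meaningful when the GPS error
  ## keeps the likelihood finite there)
  if (min(pc$b[idx]) > 0 &&
      .bridgeNll(0, pc, idx) <= o$objective)
    list(minimum = 0, objective = .bridgeNll(0, pc, idx))
  else o
}

#' Estimate the dBBMM motion variance series
#'
#' Slides a window of `w` fixes along the track. Within each window the
#' even-positioned fixes are scored by their leave-one-out Brownian bridge
#' likelihood (each under the bridge spanned by its two neighbours), the
#' motion variance is maximised by bounded one-dimensional search, and a
#' one-variance model is compared against two-variance models split at
#' every candidate behavioural breakpoint in the window interior; BIC
#' selects the model (ties favour the simpler one). The winning estimates
#' are assigned to the window's non-margin segments and averaged across
#' overlapping windows; segments inside the track-end margins inherit the
#' nearest estimated value.
#'
#' @param track a projected [VultureTrack-class] with `>= w` fixes (unless
#'   `static = TRUE`).
#' @param w window size in fixes (odd, `>= 5`; default 31).
#' @param margin breakpoint-free margin in fixes (`>= 3`, `2*margin < w`;
#'   default 11).
#' @param locError GPS error standard deviation in metres per axis
#'   (default 20, the transmitters' stated bound).
#' @param static estimate a single global motion variance instead of the
#'   windowed series (fallback for tracks shorter than `w`).
#' @return a [MotionVariance-class] with one `sigma2` (m^2/s) per
#'   inter-fix segment.
#' @export
estimateMotionVariance <- function(track, w = 31, margin = 11,
                                   locError = 20, static = FALSE) {
  stopifnot(is(track, "VultureTrack"))
  if (!isProjected(track)) stop("track must be projected first")
  if (w %% 2 != 1 || w < 5) stop("w must be an odd integer >= 5")
  if (margin < 3 || 2 * margin >= w)
    stop("margin must be >= 3 with 2*margin < w")
  f <- track@fixes
  n <- nrow(f)
  if (n < 3) stop("need at least 3 fixes")
  t <- as.numeric(f$timestamp)
  if (any(diff(t) <= 0)) stop("fix times must be strictly increasing")
  pc <- .bridgePrecomp(f$x, f$y, t, locError)
  mkMV <- function(s2) new("MotionVariance", birdId = track@birdId,
                           sigma2 = pmax(s2, 0),
                           segStart = f$timestamp[-n], segEnd = f$timestamp[-1],
                           windowSize = as.integer(w),
                           margin = as.integer(margin), locError = locError)
  allEven <- seq(2, n - 1, by = 2)
  if (static) return(mkMV(rep(.fitSigma2(pc, allEven)$minimum, n - 1)))
  if (n < w)
    stop("track has ", n, " fixes, fewer than the window size ", w,
         "; use static = TRUE for a single global motion variance")
  segs <- (margin + 1):(w - margin - 1)  # window-local non-margin segments
  ssum <- numeric(n - 1); scnt <- numeric(n - 1)
  for (g in 1:(n - w + 1)) {
    sc <- g + seq(1, w - 2, by = 2)   # scored fixes: local even positions
    lp <- sc - g + 1
    f1 <- .fitSigma2(pc, sc)
    m <- length(sc)
    best <- list(bic = 2 * f1$objective + log(m),
                 s = rep(f1$minimum, length(segs)))
    for (bp in lp[lp >= margin + 1 & lp <= w - margin]) {
      li <- sc[lp <= bp]; ri <- sc[lp > bp]
      if (length(li) < 2 || length(ri) < 2) next
      fl <- .fitSigma2(pc, li); fr <- .fitSigma2(pc, ri)
      bic2 <- 2 * (fl$objective + fr$objective) + 2 * log(m)
      if (bic2 < best$bic - 1e-9)
        best <- list(bic = bic2,
                     s = ifelse(segs <= bp - 1, fl$minimum, fr$minimum))
    }
    gs <- g + segs - 1
    ssum[gs] <- ssum[gs] + best$s
    scnt[gs] <- scnt[gs] + 1
  }
  s2 <- ifelse(scnt > 0, ssum / pmax(scnt, 1), NA_real_)
  ## margins at the track ends: carry the nearest estimate outwards
  est <- which(!is.na(s2))
  if (!length(est)) stop("no segments received a motion-variance estimate")
  s2[seq_len(min(est) - 1)] <- s2[min(est)]
  if (max(est) < length(s2)) s2[(max(est) + 1):length(s2)] <- s2[max(est)]
  mkMV(s2)
}

#' Build a raster grid covering tracks
#'
#' The origin is snapped to a multiple of `cellSize`, so all grids with
#' equal cell size share one absolute lattice and their isopleths are
#' directly comparable.
#'
#' @param tracks a projected [VultureTrack-class] or list of them.
#' @param cellSize cell edge in metres (default 500).
#' @param buffer margin around the fixes' bounding box in metres; choose
#'   at least 3 bridge standard deviations (the [computeUD()] default
#'   does).
#' @return a [GridSpec-class].
#' @export
makeGrid <- function(tracks, cellSize = 500, buffer = 3000) {
  if (is(tracks, "VultureTrack")) tracks <- list(tracks)
  xs <- unlist(lapply(tracks, function(tr) tr@fixes$x))
  ys <- unlist(lapply(tracks, function(tr) tr@fixes$y))
  if (!length(xs) || anyNA(xs)) stop("tracks must be projected and non-empty")
  x0 <- floor((min(xs) - buffer) / cellSize) * cellSize
  y0 <- floor((min(ys) - buffer) / cellSize) * cellSize
  nCols <- max(1L, as.integer(ceiling((max(xs) + buffer - x0) / cellSize)))
  nRows <- max(1L, as.integer(ceiling((max(ys) + buffer - y0) / cellSize)))
  new("GridSpec", x0 = x0, y0 = y0, cellSize = cellSize,
      nCols = nCols, nRows = nRows)
}

## mass of an isotropic Gaussian (mean mx,my, per-axis sd s) integrated
## over grid cells; returns NULL if the support misses the grid
.alphaMass <- function(grid, mx, my, s) {
  cs <- grid@cellSize
  s <- max(s, 1e-9)
  r <- 6 * s + cs
  i0 <- max(1L, as.integer(floor((mx - r - grid@x0) / cs)) + 1L)
  i1 <- min(grid@nCols, as.integer(floor((mx + r - grid@x0) / cs)) + 1L)
  j0 <- max(1L, as.integer(floor((my - r - grid@y0) / cs)) + 1L)
  j1 <- min(grid@nRows, as.integer(floor((my + r - grid@y0) / cs)) + 1L)
  if (i0 > i1 || j0 > j1) return(NULL)
  xe <- grid@x0 + (seq(i0 - 1L, i1) * cs)
  ye <- grid@y0 + (seq(j0 - 1L, j1) * cs)
  px <- diff(pnorm(xe, mx, s))
  py <- diff(pnorm(ye, my, s))
  list(i0 = i0, i1 = i1, j0 = j0, j1 = j1, mass = outer(py, px))
}

.alphaSteps <- function(K, cs, smid, dist) {
  ## refine the time discretisation when the bridge mean moves farther per
  ## step than the blob width can smooth over (narrow bridge, long hop)
  step <- max(cs, 2 * smid)
  min(50L, max(K, ceiling(dist / step)))
}

#' Brownian bridge occupation density for one segment
#'
#' Integrates the bridge's Gaussian position distribution over `K`
#' midpoint time steps onto the grid. The returned matrix sums to 1 (up to
#' mass truncated at the grid edge).
#'
#' @param p1,p2 numeric `c(x, y)` segment endpoints in metres.
#' @param T segment duration in seconds (> 0).
#' @param sigma2 motion variance in m^2/s.
#' @param delta1,delta2 endpoint GPS error SDs in metres.
#' @param grid a [GridSpec-class].
#' @param K number of midpoint time steps (`>= 5`; raised automatically
#'   when the cell size exceeds the mid-bridge standard deviation).
#' @return matrix of cell masses (`nRows` x `nCols`).
#' @export
bridgeDensity <- function(p1, p2, T, sigma2, delta1 = 0, delta2 = 0,
                          grid, K = 10) {
  if (T <= 0) stop("segment duration T must be > 0")
  if (K < 5) stop("K must be >= 5")
  W <- matrix(0, grid@nRows, grid@nCols)
  smid <- sqrt(T * 0.25 * sigma2 + 0.25 * delta1^2 + 0.25 * delta2^2)
  K <- .alphaSteps(K, grid@cellSize, smid,
                   sqrt(sum((p2 - p1)^2)))
  for (k in seq_len(K)) {
    al <- (k - 0.5) / K
    v <- T * al * (1 - al) * sigma2 + (1 - al)^2 * delta1^2 + al^2 * delta2^2
    am <- .alphaMass(grid, (1 - al) * p1[1] + al * p2[1],
                     (1 - al) * p1[2] + al * p2[2], sqrt(v))
    if (!is.null(am))
      W[am$j0:am$j1, am$i0:am$i1] <-
        W[am$j0:am$j1, am$i0:am$i1] + am$mass / K
  }
  W
}

#' Compute the dBBMM utilization distribution
#'
#' Sums per-segment Brownian bridge densities, each weighted by its
#' segment duration, skipping segments longer than `maxGap` (overnight and
#' transmission holes must not be bridged), and renormalises the raster to
#' total mass 1 (absorbing edge truncation).
#'
#' @param track a projected [VultureTrack-class]; normally the diurnal
#'   fixes of a cleaned track.
#' @param mvs a [MotionVariance-class] consistent with `track`; estimated
#'   with defaults when `NULL`.
#' @param grid a [GridSpec-class]; built automatically when `NULL` with a
#'   buffer of 3 maximum bridge standard deviations.
#' @param cellSize cell edge in metres used when `grid` is `NULL`.
#' @param maxGap maximum bridgeable segment duration in seconds (default
#'   12 h).
#' @param K time steps per segment, see [bridgeDensity()].
#' @return a [UDRaster-class].
#' @export
computeUD <- function(track, mvs = NULL, grid = NULL, cellSize = 500,
                      maxGap = 12 * 3600, K = 10) {
  stopifnot(is(track, "VultureTrack"))
  if (!isProjected(track)) stop("track must be projected first")
  f <- track@fixes
  n <- nrow(f)
  if (n < 2) stop("need at least 2 fixes")
  if (is.null(mvs)) mvs <- estimateMotionVariance(track)
  if (length(mvs@sigma2) != n - 1)
    stop("motion variance series does not match the track")
  t <- as.numeric(f$timestamp)
  dt <- diff(t)
  keep <- which(dt > 0 & dt <= maxGap)
  if (!length(keep)) stop("all segments exceed maxGap; nothing to bridge")
  delta <- mvs@locError
  if (is.null(grid)) {
    smax <- sqrt(max(dt[keep] * 0.25 * mvs@sigma2[keep]) + delta^2)
    grid <- makeGrid(track, cellSize,
                     buffer = max(3 * smax, 3 * cellSize))
  }
  W <- matrix(0, grid@nRows, grid@nCols)
  cs <- grid@cellSize
  for (i in keep) {
    s2 <- mvs@sigma2[i]
    smid <- sqrt(dt[i] * 0.25 * s2 + 0.5 * delta^2)
    Ki <- .alphaSteps(K, cs, smid,
                      sqrt((f$x[i + 1] - f$x[i])^2 +
                             (f$y[i + 1] - f$y[i])^2))
    wk <- dt[i] / Ki
    for (k in seq_len(Ki)) {
      al <- (k - 0.5) / Ki
      v <- dt[i] * al * (1 - al) * s2 + ((1 - al)^2 + al^2) * delta^2
      am <- .alphaMass(grid, (1 - al) * f$x[i] + al * f$x[i + 1],
                       (1 - al) * f$y[i] + al * f$y[i + 1], sqrt(v))
      if (!is.null(am))
        W[am$j0:am$j1, am$i0:am$i1] <-
          W[am$j0:am$j1, am$i0:am$i1] + wk * am$mass
    }
  }
  tot <- sum(W)
  if (tot <= 0) stop("UD has zero mass on the grid")
  ud <- new("UDRaster", grid = grid, weights = W / tot,
            projection = track@projection)
  attr(ud, "nSkipped") <- (n - 1) - length(keep)
  ud
}

#' Extract a UD isopleth
#'
#' Sorts cells by weight (descending, ties broken row-major: bottom row
#' first, then left to right) and selects the smallest prefix whose
#' cumulative weight reaches `level`; the isopleth polygon is the dissolved
#' union of the selected cell squares, with no sub-cell contour
#' interpolation. The 95% isopleth is the conventional home range, the 50%
#' isopleth the core area.
#'
#' @param ud a [UDRaster-class].
#' @param level fraction of total mass in (0, 1].
#' @param birdId,season optional labels stored on the result.
#' @return an [IsoplethSet-class].
#' @export
isopleth <- function(ud, level, birdId = NA_character_,
                     season = NA_character_) {
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  g <- ud@grid
  w <- as.vector(ud@weights)        # column-major: index = (col-1)*nRows+row
  if (max(w) <= 0) stop("degenerate UD: all weights zero")
  row <- rep(seq_len(g@nRows), g@nCols)
  col <- rep(seq_len(g@nCols), each = g@nRows)
  rm_id <- (row - 1) * g@nCols + col  # row-major tie-break order
  nz <- which(w > 0)
  ord <- nz[order(-w[nz], rm_id[nz])]
  cum <- cumsum(w[ord])
  nsel <- which(cum >= level - 1e-12)[1]
  if (is.na(nsel)) nsel <- length(ord)
  sel <- ord[seq_len(nsel)]
  gx0 <- as.integer(round(g@x0 / g@cellSize))
  gy0 <- as.integer(round(g@y0 / g@cellSize))
  cells <- cbind(gx0 + col[sel] - 1L, gy0 + row[sel] - 1L)
  new("IsoplethSet", level = level,
      region = latticeRegion(cells, g@cellSize),
      birdId = birdId, season = season)
}

#' Merge home ranges
#'
#' Geometric union of isopleth sets sharing a level and cell size -- the
#' "total home range" across birds, seasons or years.
#'
#' @param sets list of [IsoplethSet-class] (or [LatticeRegion-class]).
#' @return an [IsoplethSet-class] holding the dissolved union.
#' @export
unionRanges <- function(sets) {
  if (!length(sets)) stop("no isopleth sets supplied")
  if (is(sets, "IsoplethSet") || is(sets, "LatticeRegion")) sets <- list(sets)
  lev <- unique(vapply(sets, function(s)
    if (is(s, "IsoplethSet")) s@level else NA_real_, numeric(1)))
  lev <- lev[!is.na(lev)]
  if (length(lev) > 1) stop("isopleth sets have different levels")
  new("IsoplethSet", level = if (length(lev)) lev else 1,
      region = latticeUnion(sets), birdId = NA_character_,
      season = NA_character_)
}

#' Seasonal overlap of home ranges
#'
#' Pairwise and joint intersections of seasonal isopleth sets, to
#' highlight areas important across seasons.
#'
#' @param sets named list (by season) of [IsoplethSet-class].
#' @return list with `pairs` (data.frame: `season_a`, `season_b`,
#'   `area_km2`), `pairRegions`, `joint` (the all-season intersection) and
#'   `jointAreaKm2`.
#' @export
overlapSeasonal <- function(sets) {
  if (length(sets) < 2) stop("need at least two seasonal sets")
  nm <- names(sets) %||% paste0("season_", seq_along(sets))
  cmb <- utils::combn(seq_along(sets), 2)
  pairRegions <- list()
  pairs <- data.frame(season_a = character(), season_b = character(),
                      area_km2 = numeric())
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    reg <- latticeIntersect(sets[[i]], sets[[j]])
    pairRegions[[paste(nm[i], nm[j], sep = ":")]] <- reg
    pairs <- rbind(pairs, data.frame(season_a = nm[i], season_b = nm[j],
                                     area_km2 = areaKm2(reg)))
  }
  joint <- latticeIntersect(sets)
  list(pairs = pairs, pairRegions = pairRegions, joint = joint,
       jointAreaKm2 = areaKm2(joint))
}
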