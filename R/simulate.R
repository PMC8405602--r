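## Synthetic Griffon Vulture telemetry with known ground truth.
##
## The latent movement model is deliberately simple but captures the
## features the pipeline must recover: birds alternate area-restricted
## residence near an attraction centre (a discretised mean-reverting
## Ornstein-Uhlenbeck walk with exact transition variance) with occasional
## straight constant-speed commutes to another centre; nights are spent at
## the current centre (which creates roost clusters); transmitters emit a
## fix every `cadence` seconds during the device duty window and add
## isotropic Gaussian GPS noise.

#' Synthetic tracking study configuration
#'
#' Defaults emulate the structure of a multi-month Balkan tracking
#' programme at a testable scale: six birds over 120 days around three
#' attraction centres ~100-200 km apart, 10-minute fixes during a
#' 05:00-20:00 local duty cycle, residence with ~5 km stationary spread
#' inside 15-km zone discs, a 5% daily commute probability at 15 m/s, and
#' 10 m per-axis GPS noise (total error comfortably below 20 m).
#'
#' @param nBirds number of birds.
#' @param days tracking duration in days.
#' @param start first tracking date (local).
#' @param centres data.frame of attraction-centre `lon`, `lat`.
#' @param radius true zone-disc radius (m).
#' @param theta attraction strength of the mean-reverting walk (1/s).
#' @param sigmaRes residence diffusion rate (m^2/s per axis); the
#'   stationary positional sd per axis is `sqrt(sigmaRes / (2 * theta))`.
#' @param pCommute per-day probability of a commute to another centre.
#' @param commuteRates optional Z x Z matrix of per-day directed commute
#'   probabilities overriding `pCommute` (diagonal ignored).
#' @param speed commute flight speed (m/s).
#' @param departHour local clock hour at which commutes depart.
#' @param cadence fix interval (s).
#' @param deviceWindow transmitter duty hours, local clock.
#' @param window diurnal analysis window, local clock.
#' @param utcOffset fixed UTC offset (hours).
#' @param gpsNoise GPS error sd per axis (m).
#' @param crs working projection for the latent simulation.
#' @param seed RNG seed; a fixed seed reproduces the fix tables exactly.
#' @return list with class `"simConfig"`.
#' @export
simConfig <- function(nBirds = 6, days = 120, start = "2020-03-01",
                      centres = data.frame(
                        lon = c(23.15, 25.60, 23.50),
                        lat = c(41.80, 41.62, 43.20)),
                      radius = 15000, theta = 1e-4, sigmaRes = 5000,
                      pCommute = 0.05, commuteRates = NULL, speed = 15,
                      departHour = 9, cadence = 600,
                      deviceWindow = c(5, 20), window = c(6, 18),
                      utcOffset = 2, gpsNoise = 10, crs = laeaCRS(),
                      seed = 1) {
  cfg <- list(nBirds = nBirds, days = days, start = as.Date(start),
              centres = centres, radius = radius, theta = theta,
              sigmaRes = sigmaRes, pCommute = pCommute,
              commuteRates = commuteRates, speed = speed,
              departHour = departHour, cadence = cadence,
              deviceWindow = deviceWindow, window = window,
              utcOffset = utcOffset, gpsNoise = gpsNoise, crs = crs,
              seed = seed)
  class(cfg) <- "simConfig"
  stopifnot(nBirds >= 1, days >= 1, nrow(centres) >= 1, radius > 0,
            theta > 0, sigmaRes >= 0, speed > 0, cadence > 0,
            gpsNoise >= 0)
  z <- nrow(centres)
  if (z > 1) {
    p <- laeaForward(centres$lon, centres$lat, crs)
    dmin <- min(dist(cbind(p$x, p$y)))
    if (dmin < 2 * radius && speed <= 0)
      warning("zone discs overlap with no commuting: ambiguous truth")
    if (dmin < 2 * radius)
      warning("zone centres closer than twice the disc radius; ",
              "true zones overlap")
  }
  cfg
}

.commuteMatrix <- function(cfg) {
  z <- nrow(cfg$centres)
  if (!is.null(cfg$commuteRates)) {
    m <- as.matrix(cfg$commuteRates)
    stopifnot(nrow(m) == z, ncol(m) == z, all(m >= 0))
    diag(m) <- 0
    return(m)
  }
  m <- matrix(if (z > 1) cfg$pCommute / (z - 1) else 0, z, z)
  diag(m) <- 0
  m
}

#' Simulate a synthetic tracking study
#'
#' Generates per-bird GPS fix streams plus the ground truth needed to
#' score the pipeline. Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @return list with
#'   \describe{
#'     \item{tracks}{named list of unprojected [VultureTrack-class] (as an
#'       ingest reader would produce them).}
#'     \item{meta}{per-bird metadata data.frame.}
#'     \item{truth}{list: `centresXY` (projected centres), `radius`,
#'       `zoneDiscs(cellSize)` closure building the true zone discs as
#'       [LatticeRegion-class], `perDay` (bird, date, latent-path category,
#'       commute pair), `commuteFractions` (per bird and centre pair),
#'       `residentSigma2` (short-time equivalent motion variance of the
#'       residence walk, m^2/s).}
#'   }
#' @export
simulateTracks <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  crs <- cfg$crs
  ctr <- laeaForward(cfg$centres$lon, cfg$centres$lat, crs)
  cx <- ctr$x; cy <- ctr$y
  z <- length(cx)
  rates <- .commuteMatrix(cfg)
  dt <- cfg$cadence
  ## exact OU transition for one fix interval
  ouA <- exp(-cfg$theta * dt)
  ouS <- sqrt(cfg$sigmaRes / (2 * cfg$theta) * (1 - ouA^2))
  dayS <- cfg$deviceWindow[1] * 3600
  dayE <- cfg$deviceWindow[2] * 3600
  secs <- seq(dayS, dayE - dt, by = dt)   # local seconds of day
  win <- cfg$window * 3600
  groups <- rep(c("wild_caught", "reintroduced", "wild_rehabilitated"),
                length.out = cfg$nBirds)
  tracks <- list(); meta <- NULL
  perDay <- NULL
  commCount <- array(0L, c(cfg$nBirds, z, z))
  for (b in seq_len(cfg$nBirds)) {
    home <- ((b - 1) %% z) + 1
    cur <- home
    ts <- c(); lx <- c(); ly <- c()
    dayRec <- NULL
    for (d in seq_len(cfg$days)) {
      date <- cfg$start + (d - 1)
      base <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) -
        cfg$utcOffset * 3600   # UTC epoch of local midnight
      dest <- cur
      u <- runif(1)
      pr <- rates[cur, ]
      if (z > 1 && u < sum(pr))
        dest <- which(u < cumsum(pr))[1]
      commute <- dest != cur
      if (commute) commCount[b, min(cur, dest), max(cur, dest)] <-
          commCount[b, min(cur, dest), max(cur, dest)] + 1L
      depart <- cfg$departHour * 3600
      px <- cx[cur]; py <- cy[cur]   # leaves the roost at the centre
      flight <- if (commute) {
        len <- sqrt((cx[dest] - cx[cur])^2 + (cy[dest] - cy[cur])^2)
        c(depart, depart + len / cfg$speed)
      } else c(Inf, Inf)
      dx <- numeric(length(secs)); dy <- numeric(length(secs))
      for (k in seq_along(secs)) {
        s <- secs[k]
        if (s < win[1] || s >= win[2]) {
          ## roosting: held at the current centre
          here <- if (s >= flight[2]) dest else cur
          px <- cx[here]; py <- cy[here]
        } else if (commute && s >= flight[1] && s < flight[2]) {
          fr <- (s - flight[1]) / (flight[2] - flight[1])
          px <- (1 - fr) * cx[cur] + fr * cx[dest]
          py <- (1 - fr) * cy[cur] + fr * cy[dest]
        } else {
          here <- if (commute && s >= flight[2]) dest else cur
          ## OU step toward the active centre
          px <- cx[here] + (px - cx[here]) * ouA + rnorm(1, 0, ouS)
          py <- cy[here] + (py - cy[here]) * ouA + rnorm(1, 0, ouS)
        }
        dx[k] <- px; dy[k] <- py
      }
      ts <- c(ts, base + secs)
      lx <- c(lx, dx); ly <- c(ly, dy)
      ## latent-path day category against the true discs
      diu <- secs >= win[1] & secs < win[2]
      inDisc <- rep(FALSE, sum(diu))
      for (j in seq_len(z))
        inDisc <- inDisc | ((dx[diu] - cx[j])^2 + (dy[diu] - cy[j])^2 <=
                              cfg$radius^2)
      fin <- mean(inDisc)
      dayRec <- rbind(dayRec, data.frame(
        bird_id = sprintf("sim%02d", b), date = date,
        fraction_in = fin,
        category = if (fin > 0.95) "inside" else if (fin == 0) "outside"
                   else "partial",
        commute = commute,
        from = if (commute) cur else NA_integer_,
        to = if (commute) dest else NA_integer_))
      cur <- dest
    }
    ex <- lx + rnorm(length(lx), 0, cfg$gpsNoise)
    ey <- ly + rnorm(length(ly), 0, cfg$gpsNoise)
    ll <- laeaInverse(ex, ey, crs)
    id <- sprintf("sim%02d", b)
    fx <- data.frame(bird_id = id,
                     timestamp = as.POSIXct(ts, origin = "1970-01-01",
                                            tz = "UTC"),
                     lon = ll$lon, lat = ll$lat)
    rd <- if (groups[b] == "wild_caught") as.Date(NA) else cfg$start - 60
    tracks[[id]] <- makeTrack(fx, id, releaseDate = rd,
                              captureGroup = groups[b],
                              taggingLocation = "sim")
    meta <- rbind(meta, data.frame(bird_id = id, release_date = rd,
                                   capture_group = groups[b],
                                   tagging_location = "sim"))
    perDay <- rbind(perDay, dayRec)
  }
  cf <- NULL
  for (b in seq_len(cfg$nBirds))
    for (i in seq_len(z)) for (j in seq_len(z)) if (i < j)
      cf <- rbind(cf, data.frame(bird_id = sprintf("sim%02d", b),
                                 from = i, to = j,
                                 commute_days = commCount[b, i, j],
                                 fraction = commCount[b, i, j] / cfg$days))
  radius <- cfg$radius
  truth <- list(
    centresXY = cbind(x = cx, y = cy), radius = radius,
    zoneDiscs = function(cellSize)
      lapply(seq_len(z), function(j)
        latticeDisc(cx[j], cy[j], radius, cellSize)),
    perDay = perDay, commuteFractions = cf,
    ## BM motion variance matching the residence walk's one-step variance
    residentSigma2 = cfg$sigmaRes / (2 * cfg$theta) *
      (1 - exp(-2 * cfg$theta * dt)) / dt,
    stationarySd = sqrt(cfg$sigmaRes / (2 * cfg$theta)))
  list(tracks = tracks, meta = meta, truth = truth, config = cfg)
}

#' Simulate a plain Brownian-motion track
#'
#' A projected track following two-dimensional Brownian motion with known
#' motion variance, for calibration of [estimateMotionVariance()].
#'
#' @param n number of fixes.
#' @param sigma2 true motion variance (m^2/s).
#' @param dt fix interval (s).
#' @param locError GPS noise sd per axis (m) added to the emitted fixes.
#' @param origin starting point `c(x, y)` metres.
#' @param start first timestamp.
#' @param crs working projection (for back-filled lon/lat).
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return a projected [VultureTrack-class].
#' @export
simulateBrownianTrack <- function(n, sigma2, dt = 600, locError = 0,
                                  origin = c(0, 0),
                                  start = "2020-06-01 04:00:00",
                                  crs = laeaCRS(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd1 <- sqrt(sigma2 * dt)
  x <- origin[1] + cumsum(c(0, rnorm(n - 1, 0, sd1))) +
    rnorm(n, 0, locError)
  y <- origin[2] + cumsum(c(0, rnorm(n - 1, 0, sd1))) +
    rnorm(n, 0, locError)
  ts <- as.POSIXct(start, tz = "UTC") + (0:(n - 1)) * dt
  ll <- laeaInverse(x, y, crs)
  f <- data.frame(timestamp = ts, lon = ll$lon, lat = ll$lat, x = x, y = y)
  tr <- new("VultureTrack", birdId = "bm", fixes = f,
            releaseDate = as.Date(NA), captureGroup = NA_character_,
            taggingLocation = NA_character_, projection = unclass(crs))
  tr
}

#' Write a simulated study to CSV
#'
#' Emits the fix and metadata files in the dialect [readFixes()] and
#' [readBirdMeta()] read, so the full pipeline can be exercised from
#' files.
#'
#' @param sim result of [simulateTracks()].
#' @param dir output directory (created if needed).
#' @return character vector with the two file paths, invisibly.
#' @export
writeSimulatedCSV <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fixes <- do.call(rbind, lapply(sim$tracks, function(tr) {
    f <- tr@fixes
    data.frame(bird_id = tr@birdId,
               timestamp = format(f$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               lon = f$lon, lat = f$lat)
  }))
  fp <- file.path(dir, "fixes.csv")
  mp <- file.path(dir, "birds.csv")
  write.csv(fixes, fp, row.names = FALSE)
  write.csv(sim$meta, mp, row.names = FALSE)
  invisible(c(fixes = fp, meta = mp))
}

#' Score pipeline outputs against simulation truth
#'
#' @param sim result of [simulateTracks()].
#' @param zones optional inferred [VultureZoneSet-class].
#' @param classifications optional data.frame from [classifyDays()].
#' @param threshold movement-linkage threshold used, for the expected
#'   zone count.
#' @return list with `nCentres`, `expectedZones` (true zone count implied
#'   by the realised commute fractions and the threshold),
#'   `inferredZones`, `categoryAccuracy`, and `confusion` (truth in rows,
#'   inferred in columns) where computable.
#' @export
truthScorecard <- function(sim, zones = NULL, classifications = NULL,
                           threshold = 0.05) {
  cf <- sim$truth$commuteFractions
  z <- nrow(sim$config$centres)
  g <- igraph::make_empty_graph(n = z, directed = FALSE)
  if (!is.null(cf) && nrow(cf)) {
    agg <- aggregate(fraction ~ from + to, cf, max)
    link <- agg[agg$fraction > threshold, , drop = FALSE]
    if (nrow(link))
      g <- igraph::add_edges(g, as.vector(rbind(link$from, link$to)))
  }
  out <- list(nCentres = z,
              expectedZones = igraph::components(g)$no,
              inferredZones = if (!is.null(zones)) length(zones@zoneIds)
                              else NA_integer_)
  if (!is.null(classifications)) {
    key <- paste(classifications$bird_id, classifications$date)
    tkey <- paste(sim$truth$perDay$bird_id, sim$truth$perDay$date)
    m <- match(tkey, key)
    ok <- !is.na(m)
    tt <- sim$truth$perDay$category[ok]
    ii <- classifications$category[m[ok]]
    out$categoryAccuracy <- mean(tt == ii)
    out$confusion <- table(truth = tt, inferred = ii)
  }
  out
}
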