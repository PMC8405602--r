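test_that("readFixes maps columns, skips malformed rows, honours strict mode", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,when,longitude,latitude",
               "b1,2020-05-01T06:00:00,23.1,41.8",
               "b1,2020-05-01T06:10:00,23.2,41.9",
               "b2,2020-05-01T06:00:00,23.0,41.7"), path)
  dia <- fixDialect(id = "id", timestamp = "when", lon = "longitude",
                    lat = "latitude")
  fx <- suppressMessages(readFixes(path, dia))
  expect_equal(nrow(fx), 3)
  expect_s3_class(fx$timestamp, "POSIXct")
  expect_equal(fx$bird_id, c("b1", "b1", "b2"))

  # empty file with header
  writeLines("id,when,longitude,latitude", path)
  expect_equal(nrow(suppressMessages(readFixes(path, dia))), 0)

  # missing mapped column is a configuration error
  expect_error(suppressMessages(readFixes(path, fixDialect())),
               "lacks mapped column")

  # 100 rows, 2 malformed timestamps: row-by-row validity oracle
  set.seed(42)
  ts <- format(as.POSIXct("2020-05-01", tz = "UTC") + (1:100) * 600,
               "%Y-%m-%dT%H:%M:%S")
  ts[c(17, 58)] <- c("not-a-time", "2020-13-45T99:00:00")
  lon <- round(runif(100, 22, 24), 5); lat <- round(runif(100, 41, 43), 5)
  writeLines(c("bird_id,timestamp,lon,lat",
               paste("b1", ts, lon, lat, sep = ",")), path)
  oracleOK <- !is.na(strptime(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  expect_warning(fx <- suppressMessages(readFixes(path)), "2 malformed")
  expect_equal(nrow(fx), sum(oracleOK))
  expect_equal(nrow(fx), 98)
  expect_error(suppressMessages(readFixes(path, strict = TRUE)),
               "malformed")
})

test_that("deduplicate keeps the first record per timestamp", {
  t0 <- as.POSIXct("2020-05-01 06:00:00", tz = "UTC")
  fx <- data.frame(bird_id = "b", timestamp = t0 + c(0, 0, 600),
                   lon = c(23, 23, 23.01), lat = c(42, 42, 42.01))
  tr <- deduplicate(makeTrack(fx))
  expect_equal(nFixes(tr), 2)

  # no duplicates: identity
  tr2 <- mkLonLatTrack(c(23, 23.01), c(42, 42.01))
  expect_equal(fixTable(deduplicate(tr2)), fixTable(tr2))

  # 500 fixes, 37 injected duplicate timestamps: brute-force pairwise oracle
  set.seed(7)
  times <- t0 + (1:500) * 600
  ## non-adjacent injection sites, so each one duplicates its predecessor
  dupAt <- sort(sample(seq(2, 500, by = 2), 37))
  times[dupAt] <- times[dupAt - 1]
  fx <- data.frame(bird_id = "b", timestamp = times,
                   lon = runif(500, 22, 24), lat = runif(500, 41, 43))
  oracle <- sum(!vapply(seq_along(times), function(i)
    any(as.numeric(times[seq_len(i - 1)]) == as.numeric(times[i])),
    logical(1)))
  tr <- deduplicate(makeTrack(fx))
  expect_equal(nFixes(tr), oracle)
  expect_equal(nFixes(tr), 463)
})

test_that("removeOutliers drops speed-implausible fixes", {
  # stationary track unchanged
  tr <- mkProjTrack(rep(0, 20), rep(0, 20))
  expect_equal(nFixes(removeOutliers(tr)), 20)

  # teleport 500 km in 10 min is removed
  x <- c(0, 100, 5e5, 200, 300)
  tr <- mkProjTrack(x, rep(0, 5))
  out <- removeOutliers(tr, 120)
  expect_equal(nFixes(out), 4)
  expect_false(5e5 %in% fixTable(out)$x)

  # 5 spikes at 10x threshold: sequential-scan oracle
  set.seed(11)
  n <- 300
  # ~7 km/h wander, far below the 120 km/h default
  x <- cumsum(rnorm(n, 0, 50)); y <- cumsum(rnorm(n, 0, 50))
  spikes <- c(40, 90, 140, 200, 260)
  x[spikes] <- x[spikes] + 120 / 3.6 * 600 * 10
  tr <- mkProjTrack(x, y)
  out <- removeOutliers(tr, 120)
  expect_equal(nFixes(out), n - 5)
  expect_equal(attr(out, "nRemoved"), 5L)

  # a fully sub-threshold track loses nothing (any seed)
  for (s in 1:5) {
    set.seed(s)
    x <- cumsum(rnorm(200, 0, 100)); y <- cumsum(rnorm(200, 0, 100))
    expect_equal(nFixes(removeOutliers(mkProjTrack(x, y), 120)), 200)
  }

  expect_error(removeOutliers(tr, -5), "positive")
})

test_that("acclimatisation filter is strict at release + nDays", {
  rel <- as.Date("2020-01-01")
  times <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC") +
    c(50 * 86400,            # exactly release + 50 d: excluded
      50 * 86400 + 1,        # just after: retained
      51 * 86400)            # retained
  tr <- mkLonLatTrack(c(23, 23, 23), c(42, 42, 42), times,
                      releaseDate = rel, captureGroup = "reintroduced")
  out <- acclimatisationFilter(tr, 50)
  expect_equal(nFixes(out), 2)
  expect_true(all(fixTable(out)$timestamp > times[1]))

  # wild-caught bird (no release date): unchanged
  trw <- mkLonLatTrack(c(23, 23), c(42, 42), times[1:2])
  expect_equal(fixTable(acclimatisationFilter(trw)), fixTable(trw))
})

test_that("clipToRegion agrees with an independent point-in-polygon oracle", {
  region <- balkanRegion()
  # all inside
  tr <- mkLonLatTrack(c(23, 24, 25), c(41, 42, 43))
  expect_equal(nFixes(clipToRegion(tr, region)), 3)
  # all outside (Middle East)
  trME <- mkLonLatTrack(c(36, 37, 38), c(33, 33.5, 34))
  expect_equal(nFixes(clipToRegion(trME, region)), 0)

  # fixture straddling the boundary vs mgcv::in.out
  set.seed(3)
  lon <- runif(400, 10, 32); lat <- runif(400, 33, 50)
  tr <- mkLonLatTrack(lon, lat)
  kept <- nFixes(clipToRegion(tr, region))
  ring <- region@rings[[1]]
  oracle <- sum(mgcv::in.out(rbind(ring, ring[1, ]), cbind(lon, lat)))
  expect_equal(kept, oracle)
})

test_that("projection round-trips and rejects invalid coordinates", {
  p <- laeaForward(20, 42, laeaCRS(20, 42))
  expect_equal(c(p$x, p$y), c(0, 0), tolerance = 1e-9)

  set.seed(5)
  lon <- runif(1000, 13, 29); lat <- runif(1000, 35, 48)
  fw <- laeaForward(lon, lat)
  inv <- laeaInverse(fw$x, fw$y)
  expect_lt(max(abs(inv$lon - lon), abs(inv$lat - lat)), 1e-6)

  expect_error(laeaForward(20, 91), "out of range")
  expect_error(makeTrack(data.frame(bird_id = "b",
                                    timestamp = Sys.time(),
                                    lon = 20, lat = 91)), "WGS84")
  tr <- mkLonLatTrack(c(23, 24), c(42, 42.5))
  expect_error(projectTrack(tr, crs = list(lon0 = 20)), "projection")
  tr <- projectTrack(tr)
  expect_true(isProjected(tr))
  expect_false(anyNA(fixTable(tr)$x))
})

test_that("cleaning operations are idempotent and removals add up", {
  set.seed(21)
  n <- 400
  t0 <- as.POSIXct("2020-04-01 04:00:00", tz = "UTC")
  times <- t0 + cumsum(sample(c(600, 600, 600, 0), n, replace = TRUE))
  lon <- 23 + cumsum(rnorm(n, 0, 0.001))
  lat <- 42 + cumsum(rnorm(n, 0, 0.001))
  lon[c(50, 150)] <- 40     # far outside the region, implies a huge speed
  fx <- data.frame(bird_id = "b", timestamp = times, lon = lon, lat = lat)
  tr0 <- projectTrack(makeTrack(fx, releaseDate = as.Date("2020-01-01"),
                                captureGroup = "reintroduced"))
  stages <- list(
    dedup = function(tr) deduplicate(tr),
    outlier = function(tr) removeOutliers(tr, 120),
    accl = function(tr) acclimatisationFilter(tr, 50),
    clip = function(tr) clipToRegion(tr, balkanRegion()))
  tr <- tr0
  counts <- nFixes(tr)
  for (s in stages) {
    tr <- s(tr)
    counts <- c(counts, nFixes(tr))
    # idempotence: applying the same filter twice changes nothing
    expect_equal(fixTable(s(tr)), fixTable(tr))
  }
  expect_true(all(diff(counts) <= 0))
  removed <- -diff(counts)
  expect_equal(sum(removed), nFixes(tr0) - nFixes(tr))
})
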