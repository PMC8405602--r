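# Helpers to build disjoint square candidate areas and tracks that visit
# them on chosen days.
sqRegion <- function(x0, w = 2000, cs = 100) {
  g <- expand.grid(ix = seq(x0 / cs, (x0 + w) / cs - 1),
                   iy = seq(0, w / cs - 1))
  latticeRegion(as.matrix(g), cs)
}

asIso <- function(region, id) {
  new("IsoplethSet", level = 0.95, region = region, birdId = id,
      season = NA_character_)
}

# one fix per listed area per day, at the area's centre
visitTrack <- function(id, dayAreas, centres, startDate = as.Date("2020-04-01")) {
  xs <- c(); ts <- c()
  for (d in seq_along(dayAreas)) {
    hrs <- 8 + seq_along(dayAreas[[d]]) - 1
    xs <- c(xs, centres[dayAreas[[d]]])
    ts <- c(ts, atLocalHours(rep(startDate + d - 1, length(hrs)), hrs))
  }
  mkProjTrack(xs, rep(1000, length(xs)),
              as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"), id = id)
}

test_that("spatial components follow polygon-intersection connectivity", {
  A <- latticeDisc(0, 0, 1000, 100)
  B <- latticeDisc(1500, 0, 1000, 100)      # overlaps A
  C <- latticeDisc(10000, 0, 1000, 100)     # far away
  ca <- spatialComponents(list(a = A, b = B, c = C))
  expect_length(zoneRegions(ca), 2)
  expect_equal(sort(zoneMembers(ca)[[1]]), c("a", "b"))
  expect_equal(zoneMembers(ca)[[2]], "c")

  ## transitivity: A-B overlap and B-C overlap joins all three
  C2 <- latticeDisc(3000, 0, 1000, 100)
  ca2 <- spatialComponents(list(a = A, b = B, c = C2))
  expect_length(zoneRegions(ca2), 1)
  expect_equal(sort(zoneMembers(ca2)[[1]]), c("a", "b", "c"))
  expect_error(spatialComponents(list()), "no home ranges")
})

test_that("30 random discs give the same components as a union-find oracle", {
  set.seed(23)
  cs <- 100
  discs <- lapply(1:30, function(i)
    latticeDisc(runif(1, 0, 20000), runif(1, 0, 20000),
                runif(1, 400, 1200), cs))
  ca <- spatialComponents(discs)
  ## oracle: union-find over pairwise closed-polygon intersection
  ## (cell sets intersect as closed squares iff within Chebyshev dist 1)
  touches <- function(r1, r2) {
    k2 <- keysOf(r2)
    for (dx in -1:1) for (dy in -1:1) {
      shifted <- griffonRanges:::cellKey(cbind(cellsOf(r1)[, 1] + dx,
                                               cellsOf(r1)[, 2] + dy))
      if (any(shifted %in% k2)) return(TRUE)
    }
    FALSE
  }
  adj <- matrix(FALSE, 30, 30)
  for (i in 1:30) for (j in 1:30)
    if (i != j) adj[i, j] <- touches(discs[[i]], discs[[j]])
  expect_equal(length(zoneRegions(ca)), unionFindComponents(adj))
})

test_that("movement linkage merges areas strictly above the 5% rule", {
  cs <- 100
  centres <- c(A = 1000, B = 21000, C = 41000)  # disjoint squares
  areas <- new("CandidateAreaSet",
               regions = list(A1 = sqRegion(0), A2 = sqRegion(20000),
                              A3 = sqRegion(40000)),
               members = list(A1 = "b1", A2 = "b1", A3 = "b1"),
               cellSize = cs)

  ## 10 of 100 tracked days touch both A and B: fraction 0.10 > 0.05
  days <- c(rep(list(c(1, 2)), 10), rep(list(1), 90))
  tr <- visitTrack("b1", days, centres)
  zs <- movementLinkage(tr, areas, 0.05)
  expect_length(zoneIds(zs), 2)
  expect_true(any(vapply(zs@componentAreas, function(x)
    setequal(x, c("A1", "A2")), logical(1))))
  rec <- zs@linkage
  expect_equal(rec$movement_days[rec$area_a == "A1" & rec$area_b == "A2"], 10)
  expect_equal(rec$tracked_days[1], 100)

  ## fraction exactly at the threshold does not merge (strict >)
  days5 <- c(rep(list(c(1, 2)), 5), rep(list(1), 95))
  zs5 <- movementLinkage(visitTrack("b1", days5, centres), areas, 0.05)
  expect_length(zoneIds(zs5), 3)

  ## transitive linkage via two birds: one zone {A,B,C}
  areas2 <- areas
  areas2@members <- list(A1 = c("b1"), A2 = c("b1", "b2"), A3 = "b2")
  trs <- list(
    visitTrack("b1", c(rep(list(c(1, 2)), 10), rep(list(1), 90)), centres),
    visitTrack("b2", c(rep(list(c(2, 3)), 10), rep(list(2), 90)), centres))
  zsT <- movementLinkage(trs, areas2, 0.05)
  expect_length(zoneIds(zsT), 1)
  expect_setequal(zsT@componentAreas[[1]], c("A1", "A2", "A3"))
  expect_setequal(zoneMembers(zsT)[[1]], c("b1", "b2"))
})

test_that("zone count refines monotonically with the threshold", {
  cs <- 100
  centres <- c(A = 1000, B = 21000, C = 41000)
  areas <- new("CandidateAreaSet",
               regions = list(A1 = sqRegion(0), A2 = sqRegion(20000),
                              A3 = sqRegion(40000)),
               members = list(A1 = "b1", A2 = "b1", A3 = "b1"),
               cellSize = cs)
  days <- c(rep(list(c(1, 2)), 20), rep(list(c(2, 3)), 8),
            rep(list(2), 72))
  tr <- visitTrack("b1", days, centres)
  nz <- vapply(c(0.01, 0.05, 0.1, 0.25, 1), function(th)
    length(zoneIds(movementLinkage(tr, areas, th))), integer(1))
  expect_true(all(diff(nz) >= 0))
  ## threshold 1 with no spatial overlap: zones are the candidate areas
  expect_equal(nz[length(nz)], 3L)
})

test_that("zone report recovers a synthetic two-zone truth", {
  cs <- 200
  zoneA <- latticeDisc(0, 0, 3000, cs)
  zoneB <- latticeDisc(40000, 0, 3000, cs)
  zones <- new("VultureZoneSet", zoneIds = c("Z1", "Z2"),
               regions = list(Z1 = zoneA, Z2 = zoneB),
               members = list(Z1 = c("b1", "b2"), Z2 = "b3"),
               componentAreas = list(Z1 = "A1", Z2 = "A2"),
               linkage = data.frame(), cellSize = cs)
  mkResident <- function(id, cx, nDays = 4) {
    set.seed(match(id, c("b1", "b2", "b3")))
    times <- atLocalHours(rep(as.Date("2020-05-01") + 0:(nDays - 1),
                              each = 60),
                          rep(seq(7, 16.9, length.out = 60), nDays))
    n <- length(times)
    mkProjTrack(cx + cumsum(rnorm(n, 0, 60)), cumsum(rnorm(n, 0, 60)),
                times, id = id)
  }
  tracks <- list(mkResident("b1", 0), mkResident("b2", 0),
                 mkResident("b3", 40000))
  rep_ <- zoneReport(zones, tracks, cellSize = cs)
  expect_equal(nrow(rep_), 2)
  expect_equal(rep_$n_birds, c(2, 1))
  expect_true(all(rep_$area50_km2 > 0))
  expect_true(all(rep_$area50_km2 < rep_$area95_km2))

  ## empty zone set: empty table
  empty <- new("VultureZoneSet", zoneIds = character(), regions = list(),
               members = list(), componentAreas = list(),
               linkage = data.frame(), cellSize = cs)
  expect_equal(nrow(zoneReport(empty, tracks)), 0)
})
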