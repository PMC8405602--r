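test_that("motion variance is ~0 for a stationary error-free track", {
  tr <- mkProjTrack(rep(0, 80), rep(0, 80))
  mv <- estimateMotionVariance(tr, locError = 0)
  expect_true(all(sigma2(mv) <= 1e-12))
  expect_true(all(sigma2(mv) >= 0))
})

test_that("motion variance recovers Brownian motion within 20% (median of 20 seeds)", {
  meds <- vapply(1:20, function(s) {
    tr <- simulateBrownianTrack(1000, 5, dt = 600, seed = 1000 + s)
    median(sigma2(estimateMotionVariance(tr, locError = 0)))
  }, numeric(1))
  expect_lt(abs(median(meds) / 5 - 1), 0.2)
})

test_that("behavioural change points separate piecewise motion variances", {
  set.seed(17)
  tr1 <- simulateBrownianTrack(500, 0.5, dt = 600)
  set.seed(18)
  tr2 <- simulateBrownianTrack(500, 10, dt = 600)
  f2 <- fixTable(tr2)
  f1 <- fixTable(tr1)
  ## concatenate: second half continues in time and space
  f2$x <- f2$x - f2$x[1] + f1$x[500]
  f2$y <- f2$y - f2$y[1] + f1$y[500]
  f2$timestamp <- f1$timestamp[500] + 600 * seq_len(500)
  tr <- tr1
  tr@fixes <- rbind(f1, f2)
  mv <- estimateMotionVariance(tr, locError = 0)
  s2 <- sigma2(mv)
  lo <- mean(s2[100:400]); hi <- mean(s2[600:900])
  expect_gt(hi / lo, 5)
  expect_true(all(is.finite(s2)) && all(s2 >= 0))
})

test_that("estimation demands enough fixes and offers a static fallback", {
  tr <- simulateBrownianTrack(20, 2, seed = 4)
  expect_error(estimateMotionVariance(tr), "static")
  mv <- estimateMotionVariance(tr, static = TRUE)
  expect_length(sigma2(mv), 19)
  expect_equal(length(unique(sigma2(mv))), 1)
  expect_error(estimateMotionVariance(simulateBrownianTrack(100, 2),
                                      w = 30), "odd")
  expect_error(estimateMotionVariance(simulateBrownianTrack(100, 2),
                                      w = 31, margin = 16), "margin")
})

test_that("bridge density is symmetric in time and traces degenerate bridges", {
  grid <- new("GridSpec", x0 = -1000, y0 = -1000, cellSize = 50,
              nCols = 60L, nRows = 40L)
  ## sigma2 = 0, no GPS error: mass only on cells crossed by the segment
  W <- bridgeDensity(c(-800, -200), c(800, 200), T = 600, sigma2 = 0,
                     delta1 = 0, delta2 = 0, grid = grid, K = 40)
  expect_equal(sum(W), 1, tolerance = 1e-9)
  hot <- which(W > 0, arr.ind = TRUE)
  ## every hot cell centre lies within one cell diagonal of the segment
  cx <- grid@x0 + (hot[, 2] - 0.5) * grid@cellSize
  cy <- grid@y0 + (hot[, 1] - 0.5) * grid@cellSize
  dseg <- abs(cy - cx * (200 - -200) / (800 - -800))
  expect_lt(max(dseg), grid@cellSize * 1.5)

  ## time symmetry with equal endpoint errors
  W1 <- bridgeDensity(c(-500, 100), c(600, -150), 600, 3, 20, 20, grid)
  W2 <- bridgeDensity(c(600, -150), c(-500, 100), 600, 3, 20, 20, grid)
  expect_equal(W1, W2, tolerance = 1e-12)

  expect_error(bridgeDensity(c(0, 0), c(1, 1), T = 0, 1, 0, 0, grid),
               "T must be")
})

test_that("bridge mass matches the closed-form Rayleigh integral", {
  ## with delta^2 = T*sigma2/2 the bridge variance is constant in alpha:
  ## v = T*sigma2*(a(1-a) + ((1-a)^2+a^2)/2) = T*sigma2/2, so the mass
  ## within radius r of a zero-length bridge is 1 - exp(-r^2/(2v))
  T <- 600; s2 <- 2; v <- T * s2 / 2
  delta <- sqrt(v)
  grid <- new("GridSpec", x0 = -200, y0 = -200, cellSize = 4,
              nCols = 100L, nRows = 100L)
  W <- bridgeDensity(c(0, 0), c(0, 0), T, s2, delta, delta, grid, K = 10)
  cx <- grid@x0 + (col(W) - 0.5) * grid@cellSize
  cy <- grid@y0 + (row(W) - 0.5) * grid@cellSize
  r2 <- cx^2 + cy^2
  for (r in c(20, 35, 60)) {
    got <- sum(W[r2 <= r^2])
    expect_equal(got, 1 - exp(-r^2 / (2 * v)), tolerance = 0.02)
  }
})

test_that("computeUD is the duration-weighted mixture of segment bridges", {
  crs <- laeaCRS()
  tr <- mkProjTrack(c(0, 400), c(0, 100))
  mv <- new("MotionVariance", birdId = "t1", sigma2 = 4,
            segStart = fixTable(tr)$timestamp[1],
            segEnd = fixTable(tr)$timestamp[2],
            windowSize = 31L, margin = 11L, locError = 20)
  grid <- new("GridSpec", x0 = -2000, y0 = -2000, cellSize = 100,
              nCols = 50L, nRows = 50L)
  ud <- computeUD(tr, mv, grid = grid)
  B <- bridgeDensity(c(0, 0), c(400, 100), 600, 4, 20, 20, grid)
  expect_equal(udWeights(ud), B / sum(B), tolerance = 1e-9)
  expect_equal(sum(udWeights(ud)), 1, tolerance = 1e-9)

  ## two equal-duration segments: UD = average of the two bridges
  tr3 <- mkProjTrack(c(0, 400, 500), c(0, 100, -200))
  mv3 <- new("MotionVariance", birdId = "t1", sigma2 = c(4, 2),
             segStart = fixTable(tr3)$timestamp[1:2],
             segEnd = fixTable(tr3)$timestamp[2:3],
             windowSize = 31L, margin = 11L, locError = 20)
  ud3 <- computeUD(tr3, mv3, grid = grid)
  B2 <- bridgeDensity(c(400, 100), c(500, -200), 600, 2, 20, 20, grid)
  mix <- (B / sum(B) + B2 / sum(B2)) / 2
  expect_equal(udWeights(ud3), mix / sum(mix), tolerance = 1e-6)
})

test_that("gap segments are excluded from bridging", {
  t0 <- as.POSIXct("2020-05-01 06:00:00", tz = "UTC")
  tr <- mkProjTrack(c(0, 100, 90e3, 90100), c(0, 0, 0, 0),
                    times = t0 + c(0, 600, 14 * 3600, 14 * 3600 + 600))
  mv <- new("MotionVariance", birdId = "t1", sigma2 = c(2, 2, 2),
            segStart = fixTable(tr)$timestamp[1:3],
            segEnd = fixTable(tr)$timestamp[2:4],
            windowSize = 31L, margin = 11L, locError = 10)
  ud <- computeUD(tr, mv, cellSize = 100)
  expect_equal(attr(ud, "nSkipped"), 1L)
  ## no mass deposited along the 90-km overnight gap
  g <- gridSpec(ud)
  mid <- 45e3
  cols <- which(abs(g@x0 + (seq_len(g@nCols) - 0.5) * g@cellSize - mid) <
                  10e3)
  expect_equal(sum(udWeights(ud)[, cols]), 0)
  expect_error(computeUD(tr, mv, maxGap = 1), "maxGap")
})

test_that("two-fix UD matches the closed-form bridge mixture within 1% TV", {
  tr <- mkProjTrack(c(0, 100), c(0, 0))
  s2 <- 5; delta <- 10; T <- 600
  mv <- new("MotionVariance", birdId = "t1", sigma2 = s2,
            segStart = fixTable(tr)$timestamp[1],
            segEnd = fixTable(tr)$timestamp[2],
            windowSize = 31L, margin = 11L, locError = delta)
  cs <- 5  # ~ sigma_bridge / 5
  grid <- new("GridSpec", x0 = -200, y0 = -200, cellSize = cs,
              nCols = 100L, nRows = 80L)
  ud <- computeUD(tr, mv, grid = grid, K = 10)
  ## oracle: density-at-centre quadrature of the same alpha mixture
  K <- 10
  cx <- grid@x0 + (col(udWeights(ud)) - 0.5) * cs
  cy <- grid@y0 + (row(udWeights(ud)) - 0.5) * cs
  Q <- matrix(0, grid@nRows, grid@nCols)
  for (k in seq_len(K)) {
    al <- (k - 0.5) / K
    v <- T * al * (1 - al) * s2 + ((1 - al)^2 + al^2) * delta^2
    mu <- c((1 - al) * 0 + al * 100, 0)
    Q <- Q + dnorm(cx, mu[1], sqrt(v)) * dnorm(cy, mu[2], sqrt(v)) *
      cs^2 / K
  }
  Q <- Q / sum(Q)
  tv <- 0.5 * sum(abs(udWeights(ud) - Q))
  expect_lt(tv, 0.01)
})

test_that("inflating the motion variance grows the home range", {
  tr <- simulateBrownianTrack(200, 3, seed = 31)
  mv <- estimateMotionVariance(tr, locError = 0)
  grid <- makeGrid(tr, cellSize = 150, buffer = 5000)
  ud1 <- computeUD(tr, mv, grid = grid)
  mv4 <- mv; mv4@sigma2 <- mv@sigma2 * 4
  ud4 <- computeUD(tr, mv4, grid = grid)
  expect_gt(areaKm2(isopleth(ud4, 0.95)), areaKm2(isopleth(ud1, 0.95)))
})

test_that("isopleth areas are stable under a half-cell grid shift", {
  tr <- simulateBrownianTrack(300, 4, seed = 41)
  mv <- estimateMotionVariance(tr, locError = 0)
  g1 <- makeGrid(tr, cellSize = 150, buffer = 4000)
  g2 <- new("GridSpec", x0 = g1@x0 + 75, y0 = g1@y0 + 75,
            cellSize = 150, nCols = g1@nCols, nRows = g1@nRows)
  a1 <- areaKm2(isopleth(computeUD(tr, mv, grid = g1), 0.95))
  a2 <- areaKm2(isopleth(computeUD(tr, mv, grid = g2), 0.95))
  expect_lt(abs(a1 - a2) / a1, 0.02)
})
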