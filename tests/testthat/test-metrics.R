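test_that("frame distances follow the Euclidean formula and gap policies", {
  expect_equal(frameDistances(cmTraj(c(0, 3), c(0, 4))), 5)
  # one missing frame bridged: uniform split of 2 cm over 2 steps
  tr <- cmTraj(c(0, NA, 2), c(0, NA, 0), status = c("auto", "gap", "auto"))
  expect_equal(frameDistances(tr, "interpolate_uniform"), c(1, 1))
  expect_equal(frameDistances(tr, "exclude"), 2)
  # a 3-frame gap: 4 equal steps
  tr2 <- cmTraj(c(0, NA, NA, NA, 6), c(0, NA, NA, NA, 8),
                status = c("auto", rep("gap", 3), "auto"))
  expect_equal(frameDistances(tr2), rep(2.5, 4))
  expect_equal(frameDistances(tr2, "exclude"), 10)
})

test_that("degenerate trajectories raise classed errors", {
  one <- cmTraj(0, 0)
  expect_error(computeMetrics(one), class = "lapMotion_insufficient_frames")
  allgap <- cmTraj(c(0, NA, NA), c(0, NA, NA),
                   status = c("auto", "gap", "gap"))
  expect_error(frameDistances(allgap), class = "lapMotion_no_data")
})

test_that("metrics match their defining ratios and counts", {
  # N = 250 at 25 fps -> T = 10 s
  th <- seq(0, 2 * pi, length.out = 250)
  m <- computeMetrics(cmTraj(cos(th), sin(th), f = 25))
  expect_equal(m@totalTime, 10)
  expect_equal(m@meanStep, m@pathLength / 249)
  expect_equal(m@meanSpeed, m@pathLength / 10)
  expect_equal(m@pathPerMinute, 6 * m@pathLength)
  # steps 0.5, 1.2, 0.9, 2.0 with d_th = 1: E = 2 (>= comparison)
  x <- cumsum(c(0, 0.5, 1.2, 0.9, 2.0))
  m2 <- computeMetrics(cmTraj(x, rep(0, 5)), metricsConfig(1))
  expect_identical(m2@extremeCount, 2L)
  expect_identical(m2@belowCount, 2L)
  # boundary step exactly at d_th counts with >=, not with strict
  xb <- c(0, 1, 1.5)
  expect_identical(computeMetrics(cmTraj(xb, c(0, 0, 0)),
                                  metricsConfig(1))@extremeCount, 1L)
  expect_identical(computeMetrics(cmTraj(xb, c(0, 0, 0)),
                                  metricsConfig(1, strictInequality = TRUE))@extremeCount, 0L)
  # D = 10 over T = 5 -> S = 2 cm/s, 120 cm/min
  m3 <- computeMetrics(cmTraj(seq(0, 10, length.out = 125), rep(0, 125),
                              f = 25))
  expect_equal(m3@meanSpeed, 2)
  expect_equal(m3@pathPerMinute, 120)
})

test_that("all metrics match a brute-force recomputation on random trajectories", {
  set.seed(123)
  for (i in 1:100) {
    N <- sample(20:200, 1)
    f <- sample(c(24, 25, 30), 1)
    x <- cumsum(rnorm(N, 0, 0.5)); y <- cumsum(rnorm(N, 0, 0.5))
    status <- rep("auto", N)
    if (i %% 3 == 0) {     # carve an interior gap
      g0 <- sample(3:(N - 4), 1); g1 <- min(N - 2, g0 + sample(1:4, 1))
      status[g0:g1] <- "gap"
    }
    pol <- if (i %% 2 == 0) "interpolate_uniform" else "exclude"
    dth <- runif(1, 0.2, 1.5)
    m <- computeMetrics(cmTraj(x, y, f, status),
                        metricsConfig(dth, gapPolicy = pol))
    o <- oracleMetrics(x, y, f, dth, status, pol)
    expect_equal(m@totalTime, o$T, tolerance = 1e-12)
    expect_equal(m@pathLength, o$D, tolerance = 1e-12)
    expect_equal(m@meanStep, o$Dbar, tolerance = 1e-12)
    expect_equal(m@meanSpeed, o$Sbar, tolerance = 1e-12)
    expect_equal(m@extremeCount, as.integer(o$E))
    expect_equal(m@belowCount, as.integer(o$below))
    expect_equal(m@pathPerMinute, o$ppm, tolerance = 1e-12)
  }
})

test_that("metrics are translation-invariant and scale-equivariant", {
  set.seed(5)
  x <- cumsum(rnorm(50)); y <- cumsum(rnorm(50))
  cfg <- metricsConfig(0.8)
  m0 <- computeMetrics(cmTraj(x, y), cfg)
  mT <- computeMetrics(cmTraj(x + 11.3, y - 7.9), cfg)
  expect_equal(as.data.frame(m0), as.data.frame(mT))
  k <- 2.5
  mk <- computeMetrics(cmTraj(k * x, k * y), metricsConfig(k * 0.8))
  expect_equal(mk@pathLength, k * m0@pathLength)
  expect_equal(mk@meanStep, k * m0@meanStep)
  expect_equal(mk@meanSpeed, k * m0@meanSpeed)
  expect_identical(mk@extremeCount, m0@extremeCount)
  expect_identical(mk@nFrames, m0@nFrames)
  expect_equal(mk@totalTime, m0@totalTime)
})

test_that("the extreme-movement count is non-increasing in the threshold", {
  set.seed(6)
  x <- cumsum(rnorm(80)); y <- cumsum(rnorm(80))
  Es <- vapply(seq(0.1, 3, by = 0.1), function(dth)
    computeMetrics(cmTraj(x, y), metricsConfig(dth))@extremeCount,
    integer(1))
  expect_true(all(diff(Es) <= 0))
  # conservation: E + below = number of steps; D = sum of distances
  d <- frameDistances(cmTraj(x, y))
  m <- computeMetrics(cmTraj(x, y), metricsConfig(1))
  expect_identical(m@extremeCount + m@belowCount, length(d))
  expect_equal(m@pathLength, sum(d))
})
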