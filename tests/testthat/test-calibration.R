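test_that("axis-aligned and isotropic line pairs give closed-form scales", {
  s <- solveAxisScales(c(10, 0), c(0, 20), 1, 1)
  expect_equal(scaleX(s), 0.1)
  expect_equal(scaleY(s), 0.05)
  s2 <- solveAxisScales(c(3, 4), c(-4, 3), 5, 5)
  expect_equal(scaleX(s2), 1)
  expect_equal(scaleY(s2), 1)
})

test_that("known anisotropic scales are recovered from random perpendicular pairs", {
  set.seed(42)
  for (i in 1:200) {
    a <- runif(1, 0.005, 0.1); b <- runif(1, 0.005, 0.1)
    theta <- runif(1, 0, 2 * pi)
    L1 <- runif(1, 0.5, 3); L2 <- runif(1, 0.5, 3)
    # cm-space perpendicular unit vectors, mapped to pixels by (1/a, 1/b)
    u <- c(cos(theta), sin(theta)); v <- c(-sin(theta), cos(theta))
    l1 <- c(L1 * u[1] / a, L1 * u[2] / b)
    l2 <- c(L2 * v[1] / a, L2 * v[2] / b)
    if (abs(l1[1] * l2[2] - l1[2] * l2[1]) < 1e-6) next  # singular layout
    s <- solveAxisScales(l1, l2, L1, L2)
    expect_equal(scaleX(s), a, tolerance = 1e-9)
    expect_equal(scaleY(s), b, tolerance = 1e-9)
  }
})

test_that("singular and inconsistent systems raise distinct errors", {
  expect_error(solveAxisScales(c(10, 0), c(20, 0), 1, 1),
               class = "lapMotion_degenerate_calibration")
  expect_error(solveAxisScales(c(0, 0), c(0, 20), 1, 1),
               class = "lapMotion_degenerate_calibration")
  expect_error(solveAxisScales(c(10, 1), c(1, 10), 1, 20),
               class = "lapMotion_inconsistent_calibration")
})

.calibTrack <- function(e, L1 = 1, L2 = 1, f = 25) {
  new("CalibrationTrack", endpoints = e, realLength1 = L1, realLength2 = L2,
      frameRate = f)
}

.constEndpoints <- function(N, l1 = c(0, 0, 10, 0), l2 = c(0, 0, 0, 20),
                            valid = rep(TRUE, N)) {
  data.frame(frame = seq_len(N),
             l1x1 = l1[1], l1y1 = l1[2], l1x2 = l1[3], l1y2 = l1[4],
             l2x1 = l2[1], l2y1 = l2[2], l2x2 = l2[3], l2y2 = l2[4],
             valid = valid)
}

test_that("constant lines give identical per-frame scales", {
  sc <- perFrameScales(.calibTrack(.constEndpoints(10)))
  expect_equal(sc$sx, rep(0.1, 10))
  expect_equal(sc$sy, rep(0.05, 10))
})

test_that("invalid frames inherit the nearest preceding valid scale", {
  e <- .constEndpoints(10)
  e[5:7, 2:9] <- NA; e$valid[5:7] <- FALSE
  e[8:10, c("l1x2", "l2y2")] <- c(20, 20, 20, 40, 40, 40)  # zoomed 2x
  e[8:10, c("l1x1", "l1y1", "l2x1", "l2y1", "l1y2", "l2x2")] <- 0
  sc <- perFrameScales(.calibTrack(e))
  expect_equal(sc$sx[5:7], rep(sc$sx[4], 3))
  expect_equal(sc$sy[5:7], rep(sc$sy[4], 3))
  expect_equal(sc$sx[8], sc$sx[1] / 2)
  # leading invalid frames fall back to the first valid frame
  e2 <- .constEndpoints(6)
  e2[1:2, 2:9] <- NA; e2$valid[1:2] <- FALSE
  sc2 <- perFrameScales(.calibTrack(e2))
  expect_equal(sc2$sx, rep(0.1, 6))
  e3 <- .constEndpoints(4, valid = rep(FALSE, 4))
  e3[, 2:9] <- NA
  expect_error(perFrameScales(.calibTrack(e3)),
               class = "lapMotion_calibration_unavailable")
})

.rawTraj <- function(x, y, f = 25, status = rep("auto", length(x))) {
  new("RawTrajectory",
      points = data.frame(frame = seq_along(x),
                          x = ifelse(status == "gap", NA, x),
                          y = ifelse(status == "gap", NA, y),
                          status = status, confidence = NA_real_),
      frameRate = f)
}

test_that("applyScaling converts pixels to cm in both modes", {
  raw <- .rawTraj(c(100, 100), c(200, 200))
  out <- applyScaling(raw, scaleFactors(0.05, 0.05))
  expect_equal(as.data.frame(out)$x, c(5, 5))
  expect_equal(as.data.frame(out)$y, c(10, 10))
  # constant per-frame scales: average and per_frame agree
  sc <- data.frame(frame = 1:2, sx = 0.05, sy = 0.05)
  a <- applyScaling(raw, sc, "average")
  b <- applyScaling(raw, sc, "per_frame")
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_error(applyScaling(raw, data.frame(frame = 1, sx = 1, sy = 1)),
               class = "lapMotion_contract")
})

test_that("zoom equivariance: k-times pixels with 1/k scales leaves cm output unchanged", {
  set.seed(7)
  x <- cumsum(rnorm(20)) + 50; y <- cumsum(rnorm(20)) + 50
  raw1 <- .rawTraj(x, y)
  raw2 <- .rawTraj(3 * x, 3 * y)
  l1 <- c(12, 5); l2 <- c(-5, 12)
  s1 <- solveAxisScales(l1, l2, 2, 2)
  s2 <- solveAxisScales(3 * l1, 3 * l2, 2, 2)
  expect_equal(scaleX(s2), scaleX(s1) / 3)
  expect_equal(scaleY(s2), scaleY(s1) / 3)
  o1 <- applyScaling(raw1, s1, "per_frame")
  o2 <- applyScaling(raw2, s2, "per_frame")
  expect_equal(as.data.frame(o1)$x, as.data.frame(o2)$x)
  expect_equal(as.data.frame(o1)$y, as.data.frame(o2)$y)
})

test_that("round-trip: forward-projected pixels calibrate back to the cm trajectory", {
  set.seed(9)
  a <- 0.031; b <- 0.017
  xcm <- cumsum(rnorm(30, 0, 0.2)) + 3
  ycm <- cumsum(rnorm(30, 0, 0.2)) + 2
  raw <- .rawTraj(xcm / a, ycm / b)
  u <- c(cos(0.6), sin(0.6)); v <- c(-sin(0.6), cos(0.6))
  L1 <- 1.3; L2 <- 0.8
  s <- solveAxisScales(c(L1 * u[1] / a, L1 * u[2] / b),
                       c(L2 * v[1] / a, L2 * v[2] / b), L1, L2)
  out <- as.data.frame(applyScaling(raw, s, "per_frame"))
  expect_equal(out$x, xcm, tolerance = 1e-10)
  expect_equal(out$y, ycm, tolerance = 1e-10)
})
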