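test_that("a stationary target is tracked with zero displacement on every frame", {
  fs <- frameSource(markerFrames(rep(50L, 8), rep(60L, 8)), 25)
  tr <- trackPoint(fs, c(50, 60))
  p <- as.data.frame(tr)
  expect_equal(p$x, rep(50, 8))
  expect_equal(p$y, rep(60, 8))
  expect_true(all(p$status == "auto"))
})

test_that("uniform translation is recovered within 0.5 px RMSE", {
  xs <- 20L + 0:29; ys <- rep(40L, 30)
  tr <- trackPoint(frameSource(markerFrames(xs, ys), 25), c(20, 40))
  p <- as.data.frame(tr)
  rmse <- sqrt(mean((p$x - xs)^2 + (p$y - ys)^2))
  expect_lt(rmse, 0.5)
})

test_that("tracking is invariant to a global additive intensity shift", {
  xs <- 20L + (0:14) * 2L; ys <- 40L + (0:14)
  base <- markerFrames(xs, ys, bg = 0.1, fg = 0.7)
  shifted <- lapply(base, function(f) f + 0.2)
  t1 <- trackPoint(frameSource(base, 25), c(20, 40))
  t2 <- trackPoint(frameSource(shifted, 25), c(20, 40))
  expect_identical(as.data.frame(t1)$x, as.data.frame(t2)$x)
  expect_identical(as.data.frame(t1)$y, as.data.frame(t2)$y)
})

test_that("occluded frames become gaps and a correction relocates the point", {
  xs <- rep(50L, 20); ys <- rep(50L, 20)
  fs <- frameSource(markerFrames(xs, ys, blank = 10:14), 25)
  tr <- trackPoint(fs, c(50, 50),
                   corrections = data.frame(frame = 15, x = 50, y = 50))
  p <- as.data.frame(tr)
  expect_true(all(p$status[10:14] == "gap"))
  expect_identical(p$status[15], "manual")
  expect_true(all(is.na(p$x[10:14])))
  expect_equal(gapRuns(tr), data.frame(start = 10L, end = 14L))
})

test_that("invalid seeds and unrecoverable tracking raise classed errors", {
  fs <- frameSource(markerFrames(rep(50L, 5), rep(50L, 5)), 25)
  expect_error(trackPoint(fs, c(500, 50)), class = "lapMotion_invalid_seed")
  lost <- frameSource(markerFrames(rep(50L, 6), rep(50L, 6), blank = 2:6), 25)
  expect_error(trackPoint(lost, c(50, 50)),
               class = "lapMotion_tracking_failed")
})

test_that("semi- and fully-automatic modes agree when no frame is lost", {
  rv <- renderedClip(frames = 60L)
  s1 <- trackPoint(rv$frames, jointSeed(rv),
                   trackerConfig(mode = "semi_automatic"))
  s2 <- trackPoint(rv$frames, jointSeed(rv),
                   trackerConfig(mode = "fully_automatic"))
  expect_false(any(s1@points$status == "gap"))
  expect_identical(s1@points$x, s2@points$x)
  expect_identical(s1@points$y, s2@points$y)
})

test_that("corrections are honoured in semi-automatic mode and ignored in fully-automatic", {
  xs <- rep(50L, 10); ys <- rep(50L, 10)
  fs <- frameSource(markerFrames(xs, ys), 25)
  co <- data.frame(frame = 5, x = 60, y = 45)
  semi <- trackPoint(fs, c(50, 50), trackerConfig(), co)
  auto <- trackPoint(fs, c(50, 50), trackerConfig(mode = "fully_automatic"), co)
  expect_equal(as.data.frame(semi)[5, c("x", "y")],
               data.frame(x = 60, y = 45, row.names = 5L))
  expect_identical(as.data.frame(semi)$status[5], "manual")
  expect_equal(as.data.frame(auto)[5, c("x", "y")],
               data.frame(x = 50, y = 50, row.names = 5L))
})

test_that("line endpoints are tracked independently and static lines stay constant", {
  rv <- renderedClip(frames = 40L)
  ct <- trackLines(rv$frames, lineSeeds(rv), 1, 1)
  e <- ct@endpoints
  expect_true(all(e$valid))
  le <- rv$truth@lineEndpoints
  for (cc in c("l1x1", "l1y1", "l2x2", "l2y2"))
    expect_lt(max(abs(e[[cc]] - le[[cc]])), 1.5)
})

test_that("degenerate line seeds are rejected", {
  rv <- renderedClip(frames = 40L)
  bad <- lineSeeds(rv); bad[3:4] <- bad[1:2]   # zero-length first segment
  expect_error(trackLines(rv$frames, bad, 1, 1),
               class = "lapMotion_invalid_calibration")
  expect_error(trackLines(rv$frames, lineSeeds(rv), -1, 1),
               class = "lapMotion_invalid_calibration")
})

test_that("a lost endpoint marks the calibration frame invalid", {
  # static lines drawn manually, blanked for frames 6:8
  mk <- function(n, blank = FALSE) {
    f <- matrix(0, 100, 120)
    if (!blank) {
      f[50, 20:60] <- 0.4           # line 1 along x
      f[30:70, 40] <- 0.4           # line 2 along y
      f[48:52, 18:22] <- 0.9; f[48:52, 58:62] <- 0.8
      f[28:32, 38:42] <- 0.7; f[68:72, 38:42] <- 0.6
    }
    f
  }
  frames <- c(lapply(1:5, mk), lapply(6:8, mk, blank = TRUE),
              lapply(9:12, mk))
  ct <- trackLines(frameSource(frames, 25),
                   c(20, 50, 60, 50, 40, 30, 40, 70), 2, 2)
  expect_true(all(!ct@endpoints$valid[6:8]))
  expect_true(all(ct@endpoints$valid[c(1:5, 9:12)]))
})
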