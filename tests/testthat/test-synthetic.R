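test_that("trajectory generation is deterministic and respects its profile", {
  prof <- skillProfile(durationFrames = 200L)
  a <- generateTrajectory(prof, seed = 4)
  b <- generateTrajectory(prof, seed = 4)
  expect_identical(as.data.frame(a$trajectory), as.data.frame(b$trajectory))
  c2 <- generateTrajectory(prof, seed = 5)
  expect_false(identical(as.data.frame(a$trajectory)$x,
                         as.data.frame(c2$trajectory)$x))
})

test_that("near-zero step scale yields a near-constant trajectory with E = 0", {
  prof <- skillProfile(stepScale = 1e-9, jerkRate = 0, jerkMagnitude = 1,
                       durationFrames = 100L)
  g <- generateTrajectory(prof, seed = 1)
  expect_lt(g$metrics@pathLength, 1e-6)
  expect_identical(g$metrics@extremeCount, 0L)
})

test_that("without jerks no step exceeds the step scale", {
  prof <- skillProfile(stepScale = 0.2, jerkRate = 0, jerkMagnitude = 1,
                       durationFrames = 300L)
  g <- generateTrajectory(prof, seed = 2, config = metricsConfig(0.2001))
  expect_identical(g$metrics@extremeCount, 0L)
  expect_lte(max(frameDistances(g$trajectory)), 0.2)
})

test_that("the extreme-movement rate matches the jerk rate binomially", {
  prof <- skillProfile(stepScale = 0.1, smoothness = 0.7, jerkRate = 0.1,
                       jerkMagnitude = 1.5, durationFrames = 500L)
  rates <- vapply(1:8, function(s) {
    g <- generateTrajectory(prof, seed = s, config = metricsConfig(0.5))
    g$metrics@extremeCount / (g$metrics@nFrames - 1)
  }, numeric(1))
  n <- 8 * 499
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(rates) - 0.1), 3 * se)
})

test_that("ground-truth metrics are self-consistent with computeMetrics", {
  cfg <- metricsConfig(0.3)
  g <- generateTrajectory(skillProfile(durationFrames = 150L), seed = 3,
                          config = cfg)
  expect_equal(as.data.frame(g$metrics),
               as.data.frame(computeMetrics(g$trajectory, cfg)))
  rv <- renderedClip(frames = 40L)
  expect_equal(as.data.frame(rv$truth@trueMetrics),
               as.data.frame(computeMetrics(rv$generated$trajectory,
                                            metricsConfig(0.25))))
})

test_that("projection is the stated camera identity and zoom halves the cm/px scale", {
  tr <- cmTraj(c(3, 3.1, 3.2), c(2, 2, 2))
  cam <- cameraProfile(baseScaleX = 0.02, baseScaleY = 0.04)
  rv <- renderVideo(tr, cam, seed = 1)
  px <- rv$truth@pixelTrajectory
  expect_equal(px$x, c(3, 3.1, 3.2) / 0.02)
  expect_equal(px$y, c(2, 2, 2) / 0.04)
  camZ <- cameraProfile(zoom = c(1, 1, 2), translation = c(0, 0))
  rvZ <- renderVideo(cmTraj(c(1.2, 1.2, 1.2), c(1.2, 1.2, 1.2)), camZ,
                     seed = 1)
  expect_equal(rvZ$truth@trueScales$sx, c(0.02, 0.02, 0.01))
  le <- rvZ$truth@lineEndpoints
  len <- function(n) sqrt((le$l1x2[n] - le$l1x1[n])^2 +
                          (le$l1y2[n] - le$l1y1[n])^2)
  expect_equal(len(3), 2 * len(1))
})

test_that("frames are rendered deterministically and out-of-frame exits are caught", {
  tr <- cmTraj(c(3, 3.1), c(2, 2.1))
  a <- renderVideo(tr, cameraProfile(noiseSd = 0.05), seed = 9)
  b <- renderVideo(tr, cameraProfile(noiseSd = 0.05), seed = 9)
  expect_identical(a$frames@frames, b$frames@frames)
  far <- cmTraj(c(3, 40), c(2, 2))
  expect_error(renderVideo(far, cameraProfile(), seed = 1),
               class = "lapMotion_out_of_frame")
  ex <- renderVideo(far, cameraProfile(), seed = 1, allowExit = TRUE)
  expect_identical(ex$truth@occludedFrames, 2L)
})

test_that("cohort generation is deterministic, labelled and guarded", {
  co <- generateCohort(nExpert = 3L, nNovice = 4L,
                       expert = expertProfile(150L),
                       novice = noviceProfile(150L), seed = 21)
  expect_identical(nrow(co), 7L)
  expect_identical(sum(co$group == "expert"), 3L)
  co2 <- generateCohort(nExpert = 3L, nNovice = 4L,
                        expert = expertProfile(150L),
                        novice = noviceProfile(150L), seed = 21)
  expect_identical(co, co2)
  expect_error(generateCohort(nExpert = 1L, nNovice = 4L, seed = 1),
               class = "lapMotion_insufficient_data")
})
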