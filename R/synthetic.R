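# Ground-truthed synthetic data: smoothed random-walk trajectories in cm,
# rendered clips with a two-segment instrument and calibration lines, and
# labelled expert/novice cohorts. Everything is deterministic for a fixed
# seed, so every pipeline stage can be validated without clinical video.

# run expr under a fixed RNG seed without disturbing the caller's stream
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.unitAngle <- function(theta) c(cos(theta), sin(theta))

#' Generate a ground-truth cm trajectory for one procedure
#'
#' Seeded smoothed random walk: raw per-frame steps have magnitude
#' \code{stepScale} and uniform random direction, exponentially smoothed
#' with weight \code{smoothness} (so ordinary step magnitudes never exceed
#' \code{stepScale}); independently, with probability \code{jerkRate} a
#' frame's step is replaced by a jerk of magnitude exactly
#' \code{jerkMagnitude} in a random direction (the jerk does not enter the
#' smoother state). With a bounding box, steps that would exit have the
#' offending component reflected.
#'
#' @param profile a \linkS4class{SkillProfile}.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param start starting position \code{c(x, y)} in cm.
#' @param bounds optional box \code{c(xmin, xmax, ymin, ymax)} in cm that
#'   the trajectory must stay inside.
#' @param config \linkS4class{MetricsConfig} used for the returned true
#'   metrics.
#' @return list with \code{trajectory} (a \linkS4class{ScaledTrajectory}
#'   in cm, all frames tracked) and \code{metrics} (its
#'   \linkS4class{MotionMetrics}).
#' @export
generateTrajectory <- function(profile, seed = 1L, start = c(0, 0),
                               bounds = NULL, config = metricsConfig()) {
  stopifnot(is(profile, "SkillProfile"))
  N <- profile@durationFrames
  .withSeed(seed, {
    x <- numeric(N); y <- numeric(N)
    x[1L] <- start[1L]; y[1L] <- start[2L]
    v <- profile@stepScale * .unitAngle(stats::runif(1, 0, 2 * pi))
    s <- profile@smoothness
    for (n in 2L:N) {
      raw <- profile@stepScale * .unitAngle(stats::runif(1, 0, 2 * pi))
      v <- s * v + (1 - s) * raw
      step <- if (stats::runif(1) < profile@jerkRate)
        profile@jerkMagnitude * .unitAngle(stats::runif(1, 0, 2 * pi))
      else v
      if (!is.null(bounds)) {
        if (x[n - 1L] + step[1L] < bounds[1L] ||
            x[n - 1L] + step[1L] > bounds[2L]) {
          step[1L] <- -step[1L]; v[1L] <- -v[1L]
        }
        if (y[n - 1L] + step[2L] < bounds[3L] ||
            y[n - 1L] + step[2L] > bounds[4L]) {
          step[2L] <- -step[2L]; v[2L] <- -v[2L]
        }
      }
      x[n] <- x[n - 1L] + step[1L]
      y[n] <- y[n - 1L] + step[2L]
    }
    traj <- .scaledTrajectory(
      data.frame(frame = seq_len(N), x = x, y = y, status = "auto"),
      profile@frameRate)
    list(trajectory = traj, metrics = computeMetrics(traj, config))
  })
}

# draw a 1-px-wide line by dense sampling; pixels outside the frame are
# silently clipped
.drawLine <- function(img, x1, y1, x2, y2, value) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  t <- seq(0, 1, length.out = max(2L, ceiling(len * 2)))
  px <- round(x1 + t * (x2 - x1)); py <- round(y1 + t * (y2 - y1))
  ok <- px >= 1 & px <= ncol(img) & py >= 1 & py <= nrow(img)
  img[cbind(py[ok], px[ok])] <- value
  img
}

# draw a marker of half-side r centred at (x, y); each tracked point gets
# its own shape because NCC is invariant to intensity scaling, so markers
# must differ structurally, not just in brightness
.drawMarker <- function(img, x, y, r, value,
                        shape = c("solid", "plus", "cross", "hollow",
                                  "diamond")) {
  shape <- match.arg(shape)
  side <- 2L * r + 1L
  dy <- matrix(rep(-r:r, side), side); dx <- t(dy)
  mask <- switch(shape,
    solid = matrix(TRUE, side, side),
    plus = dy == 0L | dx == 0L,
    cross = abs(dy) == abs(dx),
    hollow = pmax(abs(dy), abs(dx)) == r,
    diamond = abs(dy) + abs(dx) <= r)
  px <- round(x) + dx[mask]; py <- round(y) + dy[mask]
  ok <- px >= 1 & px <= ncol(img) & py >= 1 & py <= nrow(img)
  img[cbind(py[ok], px[ok])] <- value
  img
}

#' Render a synthetic laparoscopic-style clip with ground truth
#'
#' Projects a cm trajectory through a camera model with per-frame zoom and
#' translation, and draws, on a dark background, a two-segment instrument:
#' a bright square joint marker at the trajectory position, a first
#' segment trailing off it, and a second segment carrying the two
#' perpendicular calibration lines of known real length (each line
#' endpoint gets its own small marker so it can be tracked). Projection:
#' \code{px = cm * zoom_n / baseScale + translation_n}, so the true
#' cm-per-pixel factors at frame n are \code{baseScale / zoom_n}.
#'
#' @param cmTraj a \linkS4class{ScaledTrajectory} (or a data.frame with
#'   columns \code{frame}, \code{x}, \code{y}) in cm.
#' @param camera a \linkS4class{CameraProfile}.
#' @param seed RNG seed for the intensity noise.
#' @param realLength1,realLength2 real lengths of the calibration lines, cm.
#' @param segmentAngle orientation of the instrument's second segment,
#'   radians (fixed over the clip; the instrument is rigid).
#' @param allowExit if \code{FALSE}, a joint or line endpoint projected
#'   outside the frame raises an out-of-frame error naming the offending
#'   frames; if \code{TRUE} those frames are rendered with whatever falls
#'   inside the image (an occlusion, exercising gap handling).
#' @param occludeFrames frames to render without the instrument entirely
#'   (tissue covering it).
#' @param decoyAt optional pixel position \code{c(x, y)}: during occluded
#'   frames a joint-lookalike marker is drawn there, emulating the
#'   structure that makes an automatic re-acquisition latch onto the
#'   wrong pixel.
#' @param config \linkS4class{MetricsConfig} for the true metrics.
#' @return list with \code{frames} (a \linkS4class{FrameSource}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @export
renderVideo <- function(cmTraj, camera = cameraProfile(), seed = 1L,
                        realLength1 = 1.0, realLength2 = 1.0,
                        segmentAngle = -0.35, allowExit = FALSE,
                        occludeFrames = integer(0), decoyAt = NULL,
                        config = metricsConfig()) {
  stopifnot(is(camera, "CameraProfile"))
  pts <- if (is(cmTraj, "ScaledTrajectory")) cmTraj@points else
    as.data.frame(cmTraj)
  fps <- if (is(cmTraj, "ScaledTrajectory")) cmTraj@frameRate else 25
  N <- nrow(pts)
  zoom <- rep_len(camera@zoom, N)
  tr <- camera@translation
  if (nrow(tr) == 1L) tr <- tr[rep(1L, N), , drop = FALSE]
  if (nrow(tr) != N)
    .err("contract", "translation must have 1 or N rows")
  w <- camera@imageWidth; h <- camera@imageHeight

  u <- .unitAngle(segmentAngle)          # second-segment direction
  wv <- c(-u[2L], u[1L])                 # its perpendicular
  a0 <- 0.55                             # cm from joint to line1's near end
                                         # (far enough that the joint marker
                                         # stays out of an endpoint template)
  shaft <- .unitAngle(segmentAngle + 2.4)  # first segment, drawn only

  # cm-space anchor points relative to the joint
  rel <- rbind(l1a = (a0) * u,
               l1b = (a0 + realLength1) * u,
               l2a = (a0 + realLength1 / 2) * u - (realLength2 / 2) * wv,
               l2b = (a0 + realLength1 / 2) * u + (realLength2 / 2) * wv)

  projX <- function(cmx, n) cmx * zoom[n] / camera@baseScaleX + tr[n, 1L]
  projY <- function(cmy, n) cmy * zoom[n] / camera@baseScaleY + tr[n, 2L]

  jointPx <- cbind(projX(pts$x, seq_len(N)), projY(pts$y, seq_len(N)))
  epPx <- array(0, c(N, 4L, 2L))
  for (k in 1:4) {
    epPx[, k, 1L] <- projX(pts$x + rel[k, 1L], seq_len(N))
    epPx[, k, 2L] <- projY(pts$y + rel[k, 2L], seq_len(N))
  }
  inside <- function(p) p[, 1L] >= 3 & p[, 1L] <= w - 2 &
                        p[, 2L] >= 3 & p[, 2L] <= h - 2
  visible <- inside(jointPx)
  for (k in 1:4) visible <- visible & inside(epPx[, k, ])
  if (!allowExit && any(!visible))
    .err("out_of_frame",
         paste("instrument leaves the frame at frames:",
               paste(utils::head(which(!visible), 10L), collapse = ", ")))
  occluded <- sort(unique(c(which(!visible), as.integer(occludeFrames))))

  markerVal <- c(0.85, 0.75, 0.65, 0.55)
  markerShape <- c("plus", "cross", "hollow", "diamond")
  frames <- .withSeed(seed, lapply(seq_len(N), function(n) {
    img <- matrix(0, h, w)
    if (!(n %in% occludeFrames)) {
      jx <- jointPx[n, 1L]; jy <- jointPx[n, 2L]
      sx <- zoom[n] / camera@baseScaleX; sy <- zoom[n] / camera@baseScaleY
      img <- .drawLine(img, jx, jy, jx + shaft[1L] * sx, jy + shaft[2L] * sy,
                       0.3)
      img <- .drawLine(img, epPx[n, 1L, 1L], epPx[n, 1L, 2L],
                       epPx[n, 2L, 1L], epPx[n, 2L, 2L], 0.35)
      img <- .drawLine(img, epPx[n, 3L, 1L], epPx[n, 3L, 2L],
                       epPx[n, 4L, 1L], epPx[n, 4L, 2L], 0.35)
      for (k in 1:4)
        img <- .drawMarker(img, epPx[n, k, 1L], epPx[n, k, 2L], 3L,
                           markerVal[k], markerShape[k])
      img <- .drawMarker(img, jx, jy, 2L, 1.0, "solid")
    } else if (!is.null(decoyAt)) {
      img <- .drawMarker(img, decoyAt[1L], decoyAt[2L], 2L, 0.9, "solid")
    }
    if (camera@noiseSd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, camera@noiseSd), h, w)
      img[img < 0] <- 0; img[img > 1] <- 1
    }
    img
  }))

  traj <- if (is(cmTraj, "ScaledTrajectory")) cmTraj else
    .scaledTrajectory(data.frame(frame = seq_len(N), x = pts$x, y = pts$y,
                                 status = "auto"), fps)
  truth <- new("GroundTruth",
    cmTrajectory = data.frame(frame = seq_len(N), x = pts$x, y = pts$y),
    pixelTrajectory = data.frame(frame = seq_len(N), x = jointPx[, 1L],
                                 y = jointPx[, 2L]),
    lineEndpoints = data.frame(frame = seq_len(N),
      l1x1 = epPx[, 1L, 1L], l1y1 = epPx[, 1L, 2L],
      l1x2 = epPx[, 2L, 1L], l1y2 = epPx[, 2L, 2L],
      l2x1 = epPx[, 3L, 1L], l2y1 = epPx[, 3L, 2L],
      l2x2 = epPx[, 4L, 1L], l2y2 = epPx[, 4L, 2L]),
    trueScales = data.frame(frame = seq_len(N),
                            sx = camera@baseScaleX / zoom,
                            sy = camera@baseScaleY / zoom),
    trueMetrics = computeMetrics(traj, config),
    occludedFrames = as.integer(occluded))
  list(frames = frameSource(frames, fps), truth = truth)
}

#' Generate a labelled expert/novice cohort of motion metrics
#'
#' Each subject's profile is jittered multiplicatively around its group
#' profile (log-normal, sd \code{jitterSd} on step scale and jerk
#' magnitude, 2 * \code{jitterSd} on jerk rate), a trajectory is generated
#' and its metrics computed. Deterministic for a fixed seed.
#'
#' @param nExpert,nNovice group sizes, each >= 2.
#' @param expert,novice the group \linkS4class{SkillProfile}s.
#' @param seed integer RNG seed.
#' @param config \linkS4class{MetricsConfig} for the per-subject metrics.
#' @param jitterSd between-subject variability (default 0.1).
#' @return data.frame with one row per subject: \code{subject},
#'   \code{group} ("expert"/"novice") and all metric columns.
#' @export
generateCohort <- function(nExpert = 6L, nNovice = 23L,
                           expert = expertProfile(),
                           novice = noviceProfile(),
                           seed = 1L, config = metricsConfig(),
                           jitterSd = 0.1) {
  if (nExpert < 2L || nNovice < 2L)
    .err("insufficient_data", "each group needs at least 2 subjects")
  groups <- c(rep("expert", nExpert), rep("novice", nNovice))
  profiles <- c(rep(list(expert), nExpert), rep(list(novice), nNovice))
  .withSeed(seed, {
    subjSeeds <- sample.int(.Machine$integer.max - 1L, length(groups))
    rows <- lapply(seq_along(groups), function(i) {
      p <- profiles[[i]]
      step <- p@stepScale * exp(stats::rnorm(1, 0, jitterSd))
      jerkM <- max(p@jerkMagnitude * exp(stats::rnorm(1, 0, jitterSd)),
                   step * 1.5)
      jerkR <- min(1, p@jerkRate * exp(stats::rnorm(1, 0, 2 * jitterSd)))
      pj <- skillProfile(step, p@smoothness, jerkR, jerkM,
                         p@durationFrames, p@frameRate)
      m <- generateTrajectory(pj, seed = subjSeeds[i], config = config)$metrics
      cbind(data.frame(subject = i, group = groups[i]), as.data.frame(m))
    })
    do.call(rbind, rows)
  })
}
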