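#' Build a FrameSource from matrices or a directory of PNG frames
#'
#' @param frames either a list of grayscale matrices (values in \[0, 1\]),
#'   a 3-d array (rows x cols x frames), or a path to a directory of
#'   numbered PNG files (read in lexicographic order; RGB frames are
#'   converted to intensity with Rec. 601 luma weights 0.299, 0.587,
#'   0.114).
#' @param frameRate frames per second.
#' @return a \linkS4class{FrameSource}.
#' @export
frameSource <- function(frames, frameRate = 25) {
  if (is.character(frames)) {
    frames <- readFramesPNG(frames)
  } else if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3L]), function(i) frames[, , i])
  } else {
    frames <- lapply(frames, .toIntensity)
  }
  new("FrameSource", frames = frames, frameRate = as.numeric(frameRate))
}

#' Tracker configuration
#'
#' Defaults: template radius 10 px, search radius 25 px, confidence floor
#' 0.5, semi-automatic mode, template refreshed after every accepted frame.
#'
#' @param templateRadius,searchRadius patch and search half-sides, pixels.
#' @param confidenceFloor NCC score below which the point is lost.
#' @param mode \code{"semi_automatic"} or \code{"fully_automatic"}.
#' @param refreshTemplate refresh the template at each accepted frame?
#' @return a \linkS4class{TrackerConfig}.
#' @export
trackerConfig <- function(templateRadius = 10L, searchRadius = 25L,
                          confidenceFloor = 0.5, mode = "semi_automatic",
                          refreshTemplate = TRUE) {
  new("TrackerConfig", templateRadius = as.integer(templateRadius),
      searchRadius = as.integer(searchRadius),
      confidenceFloor = as.numeric(confidenceFloor),
      mode = mode, refreshTemplate = isTRUE(refreshTemplate))
}

#' Metrics configuration
#'
#' @param extremeThreshold d_th in cm per frame; steps with displacement
#'   at or above it count as extreme movements. Default 1 cm; 3.5 cm is a
#'   common alternative preset for "sudden" movements.
#' @param gapPolicy \code{"interpolate_uniform"} or \code{"exclude"}.
#' @param strictInequality use d > d_th instead of d >= d_th.
#' @return a \linkS4class{MetricsConfig}.
#' @export
metricsConfig <- function(extremeThreshold = 1.0,
                          gapPolicy = "interpolate_uniform",
                          strictInequality = FALSE) {
  new("MetricsConfig", extremeThreshold = as.numeric(extremeThreshold),
      gapPolicy = gapPolicy, strictInequality = isTRUE(strictInequality))
}

#' Skill profile for the synthetic trajectory generator
#'
#' @param stepScale mean per-frame movement magnitude, cm.
#' @param smoothness exponential low-pass weight in \[0, 1).
#' @param jerkRate per-frame probability of an injected large step.
#' @param jerkMagnitude magnitude of injected steps, cm.
#' @param durationFrames number of frames.
#' @param frameRate frames per second.
#' @return a \linkS4class{SkillProfile}.
#' @export
skillProfile <- function(stepScale = 0.12, smoothness = 0.8,
                         jerkRate = 0.01, jerkMagnitude = 2.0,
                         durationFrames = 750L, frameRate = 25) {
  new("SkillProfile", stepScale = as.numeric(stepScale),
      smoothness = as.numeric(smoothness), jerkRate = as.numeric(jerkRate),
      jerkMagnitude = as.numeric(jerkMagnitude),
      durationFrames = as.integer(durationFrames),
      frameRate = as.numeric(frameRate))
}

#' Expert-like and novice-like default profiles
#'
#' Small smooth steps with rare jerks for the expert-like profile; larger,
#' less smooth steps with frequent jerks for the novice-like one. Both run
#' at 25 fps. These encode a detectable skill contrast, not any published
#' cohort's medians.
#'
#' @param durationFrames number of frames (default 750, i.e. 30 s at 25 fps).
#' @return a \linkS4class{SkillProfile}.
#' @export
expertProfile <- function(durationFrames = 750L) {
  skillProfile(stepScale = 0.12, smoothness = 0.85, jerkRate = 0.01,
               jerkMagnitude = 2.0, durationFrames = durationFrames)
}

#' @rdname expertProfile
#' @export
noviceProfile <- function(durationFrames = 750L) {
  skillProfile(stepScale = 0.18, smoothness = 0.6, jerkRate = 0.08,
               jerkMagnitude = 2.5, durationFrames = durationFrames)
}

#' Camera profile for the synthetic renderer
#'
#' @param baseScaleX,baseScaleY cm per pixel at zoom 1.
#' @param zoom per-frame zoom multipliers (length 1 or N).
#' @param translation per-frame pixel offsets: a length-2 vector or an
#'   N x 2 matrix.
#' @param imageWidth,imageHeight frame size in pixels.
#' @param noiseSd additive Gaussian intensity noise sd (intensity units,
#'   frames are clipped back to \[0, 1\]).
#' @return a \linkS4class{CameraProfile}.
#' @export
cameraProfile <- function(baseScaleX = 0.02, baseScaleY = 0.02,
                          zoom = 1, translation = c(0, 0),
                          imageWidth = 320L, imageHeight = 240L,
                          noiseSd = 0) {
  if (is.null(dim(translation)))
    translation <- matrix(translation, ncol = 2L)
  new("CameraProfile", baseScaleX = as.numeric(baseScaleX),
      baseScaleY = as.numeric(baseScaleY), zoom = as.numeric(zoom),
      translation = translation, imageWidth = as.integer(imageWidth),
      imageHeight = as.integer(imageHeight), noiseSd = as.numeric(noiseSd))
}

#' Scale factors in cm per pixel
#'
#' @param sx,sy positive cm-per-pixel factors.
#' @return a \linkS4class{ScaleFactors}.
#' @export
scaleFactors <- function(sx, sy) {
  new("ScaleFactors", sx = as.numeric(sx), sy = as.numeric(sy))
}

# internal: assemble a RawTrajectory from a points data.frame
.rawTrajectory <- function(points, frameRate) {
  rownames(points) <- NULL
  points$frame <- as.integer(points$frame)
  new("RawTrajectory", points = points, frameRate = as.numeric(frameRate))
}

# internal: assemble a ScaledTrajectory
.scaledTrajectory <- function(points, frameRate) {
  rownames(points) <- NULL
  points$frame <- as.integer(points$frame)
  new("ScaledTrajectory", points = points, frameRate = as.numeric(frameRate))
}
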