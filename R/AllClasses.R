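#' @import methods
NULL

# classed conditions so callers can distinguish failure modes
.err <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("lapMotion_", class), "lapMotionError")))
}

.warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(paste0("lapMotion_", class), "lapMotionWarning")))
}

.TRACK_STATUSES <- c("auto", "manual", "gap")

#' FrameSource: an ordered sequence of video frames
#'
#' Container for a video clip represented as a list of grayscale intensity
#' matrices (values in \[0, 1\], indexed \code{frame[row, col]} with the
#' origin at the top-left, x increasing rightwards = column, y increasing
#' downwards = row) together with the frame rate in frames per second.
#'
#' @slot frames list of numeric matrices, all with identical dimensions.
#' @slot frameRate frames per second (f > 0).
#' @export
setClass("FrameSource",
  representation(frames = "list", frameRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@frames) < 2L)
      msg <- c(msg, "a FrameSource needs at least 2 frames")
    if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
        object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (length(object@frames) >= 1L) {
      if (!all(vapply(object@frames, is.matrix, logical(1L))))
        msg <- c(msg, "all frames must be matrices")
      else {
        d <- dim(object@frames[[1L]])
        same <- vapply(object@frames, function(f) identical(dim(f), d), logical(1L))
        if (!all(same)) msg <- c(msg, "all frames must share identical dimensions")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' TrackerConfig: parameters of the template-matching tracker
#'
#' @slot templateRadius half-side of the square template patch, pixels.
#' @slot searchRadius half-side of the search window around the previous
#'   accepted location, pixels; must be at least \code{templateRadius}.
#' @slot confidenceFloor normalized cross-correlation score in \[-1, 1\]
#'   below which the point is declared lost for that frame.
#' @slot mode \code{"semi_automatic"} (lost frames become gaps until a
#'   manual correction relocates the point) or \code{"fully_automatic"}
#'   (corrections are ignored and a lost point is re-acquired as the global
#'   best match over the whole frame).
#' @slot refreshTemplate if \code{TRUE} (default) the template is re-cut
#'   around each accepted location; if \code{FALSE} the seed template is
#'   kept for the whole run.
#' @export
setClass("TrackerConfig",
  representation(templateRadius = "integer", searchRadius = "integer",
                 confidenceFloor = "numeric", mode = "character",
                 refreshTemplate = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@templateRadius < 1L)
      msg <- c(msg, "templateRadius must be >= 1")
    if (object@searchRadius < object@templateRadius)
      msg <- c(msg, "searchRadius must be >= templateRadius")
    if (object@confidenceFloor < -1 || object@confidenceFloor > 1)
      msg <- c(msg, "confidenceFloor must lie in [-1, 1]")
    if (!object@mode %in% c("semi_automatic", "fully_automatic"))
      msg <- c(msg, "mode must be 'semi_automatic' or 'fully_automatic'")
    if (length(msg)) msg else TRUE
  }
)

#' RawTrajectory: per-frame pixel coordinates of the tracked point
#'
#' One row per frame index 1..N with columns \code{frame}, \code{x},
#' \code{y} (pixels; NA on gap frames), \code{status} (one of
#' \code{auto}, \code{manual}, \code{gap}) and \code{confidence} (the NCC
#' match score, NA for manual and gap frames).
#'
#' @slot points data.frame as described above.
#' @slot frameRate frames per second.
#' @export
setClass("RawTrajectory",
  representation(points = "data.frame", frameRate = "numeric"),
  validity = function(object) {
    p <- object@points
    msg <- character()
    need <- c("frame", "x", "y", "status", "confidence")
    if (!all(need %in% names(p)))
      return(paste("points must have columns", paste(need, collapse = ", ")))
    if (!identical(as.integer(p$frame), seq_len(nrow(p))))
      msg <- c(msg, "points must carry exactly one row per frame index 1..N")
    if (!all(p$status %in% .TRACK_STATUSES))
      msg <- c(msg, "status must be auto, manual or gap")
    gap <- p$status == "gap"
    if (any(!gap & (is.na(p$x) | is.na(p$y))))
      msg <- c(msg, "non-gap frames must have coordinates")
    if (any(gap & (!is.na(p$x) | !is.na(p$y))))
      msg <- c(msg, "gap frames must have NA coordinates")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (length(msg)) msg else TRUE
  }
)

#' CalibrationTrack: per-frame endpoints of the two reference lines
#'
#' Stores, per frame, the tracked pixel endpoints of the two perpendicular
#' calibration lines drawn along the instrument's second segment, their
#' known real lengths in centimetres, and a per-frame validity flag (a
#' frame is invalid when any endpoint was lost).
#'
#' @slot endpoints data.frame with columns \code{frame}, \code{l1x1},
#'   \code{l1y1}, \code{l1x2}, \code{l1y2}, \code{l2x1}, \code{l2y1},
#'   \code{l2x2}, \code{l2y2}, \code{valid}.
#' @slot realLength1,realLength2 real lengths of the two lines, cm.
#' @slot frameRate frames per second.
#' @export
setClass("CalibrationTrack",
  representation(endpoints = "data.frame", realLength1 = "numeric",
                 realLength2 = "numeric", frameRate = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("frame", "l1x1", "l1y1", "l1x2", "l1y2",
              "l2x1", "l2y1", "l2x2", "l2y2", "valid")
    if (!all(need %in% names(object@endpoints)))
      return(paste("endpoints must have columns", paste(need, collapse = ", ")))
    if (object@realLength1 <= 0 || object@realLength2 <= 0)
      msg <- c(msg, "real line lengths must be positive")
    e <- object@endpoints
    v <- which(e$valid)
    if (length(v)) {
      len1 <- (e$l1x2[v] - e$l1x1[v])^2 + (e$l1y2[v] - e$l1y1[v])^2
      len2 <- (e$l2x2[v] - e$l2x1[v])^2 + (e$l2y2[v] - e$l2y1[v])^2
      if (any(len1 == 0) || any(len2 == 0))
        msg <- c(msg, "line vectors must be non-zero on valid frames")
    }
    if (length(msg)) msg else TRUE
  }
)

#' ScaleFactors: axis scaling in cm per pixel
#'
#' @slot sx,sy positive cm-per-pixel factors for the x and y axes.
#' @export
setClass("ScaleFactors",
  representation(sx = "numeric", sy = "numeric"),
  validity = function(object) {
    if (length(object@sx) != 1L || length(object@sy) != 1L ||
        object@sx <= 0 || object@sy <= 0)
      "sx and sy must be single positive numbers" else TRUE
  }
)

#' ScaledTrajectory: trajectory in centimetres
#'
#' Same frame count and gap structure as the source \linkS4class{RawTrajectory},
#' with coordinates in cm.
#'
#' @slot points data.frame with columns \code{frame}, \code{x}, \code{y}
#'   (cm, NA on gaps) and \code{status}.
#' @slot frameRate frames per second.
#' @export
setClass("ScaledTrajectory",
  representation(points = "data.frame", frameRate = "numeric"),
  validity = function(object) {
    p <- object@points
    need <- c("frame", "x", "y", "status")
    if (!all(need %in% names(p)))
      return(paste("points must have columns", paste(need, collapse = ", ")))
    if (!identical(as.integer(p$frame), seq_len(nrow(p))))
      return("points must carry exactly one row per frame index 1..N")
    if (object@frameRate <= 0) return("frameRate must be positive")
    TRUE
  }
)

#' MetricsConfig: parameters of the kinematic metrics
#'
#' @slot extremeThreshold d_th, the inter-frame displacement (cm per frame)
#'   at or above which a step counts as an extreme movement. Default 1 cm.
#' @slot gapPolicy \code{"interpolate_uniform"} (a bridged gap of k missing
#'   frames contributes k+1 equal steps) or \code{"exclude"} (the bridge
#'   contributes a single step counted once).
#' @slot strictInequality if \code{TRUE}, extreme steps require d > d_th
#'   rather than the default d >= d_th.
#' @export
setClass("MetricsConfig",
  representation(extremeThreshold = "numeric", gapPolicy = "character",
                 strictInequality = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@extremeThreshold <= 0)
      msg <- c(msg, "extremeThreshold must be positive")
    if (!object@gapPolicy %in% c("interpolate_uniform", "exclude"))
      msg <- c(msg, "gapPolicy must be 'interpolate_uniform' or 'exclude'")
    if (length(msg)) msg else TRUE
  }
)

#' MotionMetrics: the kinematic criteria for one procedure
#'
#' Holds, for a single tracked procedure: the frame count N, frame rate f,
#' total time T = N/f (s), path length D (cm), average movement
#' D-bar = D/(N-1) (cm/frame), average speed S-bar = D/T (cm/s), the count
#' E of extreme movements (steps with d >= d_th), the count of steps below
#' the threshold, and the path length per minute 60 D / T (cm/min).
#'
#' @slot nFrames,frameRate,totalTime,pathLength,meanStep,meanSpeed numeric.
#' @slot extremeCount,belowCount step counts.
#' @slot pathPerMinute cm per minute.
#' @slot threshold the d_th used, cm/frame.
#' @export
setClass("MotionMetrics",
  representation(nFrames = "integer", frameRate = "numeric",
                 totalTime = "numeric", pathLength = "numeric",
                 meanStep = "numeric", meanSpeed = "numeric",
                 extremeCount = "integer", belowCount = "integer",
                 pathPerMinute = "numeric", threshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@pathLength < 0) msg <- c(msg, "pathLength must be >= 0")
    if (object@extremeCount > object@nFrames - 1L)
      msg <- c(msg, "extremeCount cannot exceed N - 1")
    if (length(msg)) msg else TRUE
  }
)

#' GroupComparison: rank-based two-group comparison of one metric
#'
#' @slot metricName character name of the compared metric.
#' @slot medianA,medianB group medians in the metric's units.
#' @slot statistic the Mann-Whitney U statistic (for group A).
#' @slot pValue two-sided p-value.
#' @slot nA,nB group sizes.
#' @slot significant \code{pValue < 0.05}.
#' @slot method short description of the p-value computation path.
#' @export
setClass("GroupComparison",
  representation(metricName = "character", medianA = "numeric",
                 medianB = "numeric", statistic = "numeric",
                 pValue = "numeric", nA = "integer", nB = "integer",
                 significant = "logical", method = "character"),
  validity = function(object) {
    msg <- character()
    if (object@pValue < 0 || object@pValue > 1)
      msg <- c(msg, "pValue must lie in [0, 1]")
    if (!identical(object@significant, unname(object@pValue < 0.05)))
      msg <- c(msg, "significant must equal pValue < 0.05")
    if (length(msg)) msg else TRUE
  }
)

#' BiasReport: fully-automatic vs semi-automatic tracking agreement
#'
#' Per-procedure relative differences (auto - semi)/semi for one metric,
#' their median, and the procedures flagged as outliers.
#'
#' @slot table data.frame with columns \code{index}, \code{semi},
#'   \code{auto}, \code{relDiff}, \code{outlier}.
#' @slot medianRelDiff median relative difference across usable pairs.
#' @slot outlierThreshold |relDiff| above which a pair is flagged.
#' @export
setClass("BiasReport",
  representation(table = "data.frame", medianRelDiff = "numeric",
                 outlierThreshold = "numeric"))

#' SkillProfile: generator settings for one skill level
#'
#' Parameterizes the smoothed random walk emulating instrument-tip motion:
#' experts move in small smooth steps with rare jerks, novices in larger,
#' jerkier steps.
#'
#' @slot stepScale magnitude of raw per-frame steps, cm.
#' @slot smoothness exponential low-pass weight in \[0, 1).
#' @slot jerkRate per-frame probability of an injected large step.
#' @slot jerkMagnitude magnitude of injected steps, cm (> stepScale).
#' @slot durationFrames number of frames N.
#' @slot frameRate frames per second.
#' @export
setClass("SkillProfile",
  representation(stepScale = "numeric", smoothness = "numeric",
                 jerkRate = "numeric", jerkMagnitude = "numeric",
                 durationFrames = "integer", frameRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@stepScale <= 0) msg <- c(msg, "stepScale must be positive")
    if (object@smoothness < 0 || object@smoothness >= 1)
      msg <- c(msg, "smoothness must lie in [0, 1)")
    if (object@jerkRate < 0 || object@jerkRate > 1)
      msg <- c(msg, "jerkRate must lie in [0, 1]")
    if (object@jerkMagnitude <= object@stepScale)
      msg <- c(msg, "jerkMagnitude must exceed stepScale")
    if (object@durationFrames < 2L) msg <- c(msg, "durationFrames must be >= 2")
    if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' CameraProfile: synthetic camera model
#'
#' Maps cm coordinates to pixels with per-frame zoom and translation:
#' a point at (x, y) cm appears at column x * zoom_n / sx + tx_n + cx,
#' row y * zoom_n / sy + ty_n + cy, where (cx, cy) is the image centre.
#'
#' @slot baseScaleX,baseScaleY cm per pixel at zoom 1.
#' @slot zoom per-frame zoom multipliers (recycled if length 1).
#' @slot translation per-frame pixel offsets, a 2-column matrix (x, y)
#'   or a length-2 vector.
#' @slot imageWidth,imageHeight frame size, pixels (>= 64).
#' @slot noiseSd additive Gaussian intensity noise standard deviation.
#' @export
setClass("CameraProfile",
  representation(baseScaleX = "numeric", baseScaleY = "numeric",
                 zoom = "numeric", translation = "matrix",
                 imageWidth = "integer", imageHeight = "integer",
                 noiseSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@zoom <= 0)) msg <- c(msg, "zoom multipliers must be positive")
    if (object@imageWidth < 64L || object@imageHeight < 64L)
      msg <- c(msg, "image size must be at least 64 x 64")
    if (object@baseScaleX <= 0 || object@baseScaleY <= 0)
      msg <- c(msg, "base scales must be positive")
    if (ncol(object@translation) != 2L)
      msg <- c(msg, "translation must have 2 columns (x, y)")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' GroundTruth: everything the renderer knows about a synthetic clip
#'
#' @slot cmTrajectory data.frame \code{frame}, \code{x}, \code{y} in cm.
#' @slot pixelTrajectory data.frame \code{frame}, \code{x}, \code{y}: the
#'   continuous (unrounded) projected joint position in pixels.
#' @slot lineEndpoints data.frame with the calibration CSV schema
#'   (continuous pixel endpoints of both lines per frame).
#' @slot trueScales data.frame \code{frame}, \code{sx}, \code{sy}: the
#'   per-frame cm-per-pixel factors the camera actually applied.
#' @slot trueMetrics \linkS4class{MotionMetrics} computed from the cm
#'   trajectory.
#' @slot occludedFrames integer vector of frames rendered without the
#'   instrument (empty unless \code{allowExit} was used).
#' @export
setClass("GroundTruth",
  representation(cmTrajectory = "data.frame", pixelTrajectory = "data.frame",
                 lineEndpoints = "data.frame", trueScales = "data.frame",
                 trueMetrics = "MotionMetrics", occludedFrames = "integer"))
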