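#' Frame rate accessor
#'
#' @param x a FrameSource, RawTrajectory, ScaledTrajectory or
#'   CalibrationTrack.
#' @return frames per second.
#' @rdname frameRate
#' @export
setMethod("frameRate", "FrameSource", function(x) x@frameRate)

#' @rdname frameRate
#' @export
setMethod("frameRate", "RawTrajectory", function(x) x@frameRate)

#' @rdname frameRate
#' @export
setMethod("frameRate", "ScaledTrajectory", function(x) x@frameRate)

#' @rdname frameRate
#' @export
setMethod("frameRate", "CalibrationTrack", function(x) x@frameRate)

#' Number of frames
#'
#' @param x a FrameSource, RawTrajectory or ScaledTrajectory.
#' @return the frame count N.
#' @rdname frameCount
#' @export
setMethod("frameCount", "FrameSource", function(x) length(x@frames))

#' @rdname frameCount
#' @export
setMethod("frameCount", "RawTrajectory", function(x) nrow(x@points))

#' @rdname frameCount
#' @export
setMethod("frameCount", "ScaledTrajectory", function(x) nrow(x@points))

# maximal runs of gap status as a data.frame(start, end)
.runsOf <- function(isGap) {
  r <- rle(isGap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Maximal runs of gap frames
#'
#' @param x a RawTrajectory or ScaledTrajectory.
#' @return data.frame with columns \code{start} and \code{end} (frame
#'   indices, inclusive), one row per maximal run of \code{status == "gap"}.
#' @rdname gapRuns
#' @export
setMethod("gapRuns", "RawTrajectory", function(x) .runsOf(x@points$status == "gap"))

#' @rdname gapRuns
#' @export
setMethod("gapRuns", "ScaledTrajectory", function(x) .runsOf(x@points$status == "gap"))

#' ScaleFactors accessors
#'
#' @param x a ScaleFactors object.
#' @return the cm-per-pixel factor for the axis.
#' @rdname scaleFactors
#' @export
setMethod("scaleX", "ScaleFactors", function(x) x@sx)

#' @rdname scaleFactors
#' @export
setMethod("scaleY", "ScaleFactors", function(x) x@sy)

#' @export
#' @describeIn RawTrajectory-class coerce the per-frame points to a
#'   data.frame.
setMethod("as.data.frame", "RawTrajectory", function(x, ...) x@points)

#' @export
#' @describeIn ScaledTrajectory-class coerce the per-frame points to a
#'   data.frame.
setMethod("as.data.frame", "ScaledTrajectory", function(x, ...) x@points)

#' @export
#' @describeIn MotionMetrics-class one-row data.frame with all metric
#'   fields.
setMethod("as.data.frame", "MotionMetrics", function(x, ...) {
  data.frame(n_frames = x@nFrames, frame_rate = x@frameRate,
             total_time_s = x@totalTime, path_length_cm = x@pathLength,
             mean_step_cm = x@meanStep, mean_speed_cm_s = x@meanSpeed,
             extreme_count = x@extremeCount, below_count = x@belowCount,
             path_per_minute_cm = x@pathPerMinute, threshold_cm = x@threshold)
})

#' @export
#' @describeIn GroupComparison-class one-row data.frame summary.
setMethod("as.data.frame", "GroupComparison", function(x, ...) {
  data.frame(metric = x@metricName, median_a = x@medianA,
             median_b = x@medianB, U = x@statistic, p_value = x@pValue,
             n_a = x@nA, n_b = x@nB, significant = x@significant)
})

setMethod("show", "FrameSource", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("FrameSource: %d frames of %d x %d px at %g fps (%.1f s)\n",
              length(object@frames), d[2L], d[1L], object@frameRate,
              length(object@frames) / object@frameRate))
})

setMethod("show", "RawTrajectory", function(object) {
  s <- table(factor(object@points$status, levels = .TRACK_STATUSES))
  cat(sprintf(
    "RawTrajectory: %d frames at %g fps (auto %d, manual %d, gap %d)\n",
    nrow(object@points), object@frameRate, s[["auto"]], s[["manual"]],
    s[["gap"]]))
})

setMethod("show", "ScaledTrajectory", function(object) {
  cat(sprintf("ScaledTrajectory: %d frames at %g fps, units cm\n",
              nrow(object@points), object@frameRate))
})

setMethod("show", "CalibrationTrack", function(object) {
  cat(sprintf(
    "CalibrationTrack: %d frames (%d valid), real lengths %.3g / %.3g cm\n",
    nrow(object@endpoints), sum(object@endpoints$valid),
    object@realLength1, object@realLength2))
})

setMethod("show", "ScaleFactors", function(object) {
  cat(sprintf("ScaleFactors: sx = %.6g, sy = %.6g cm/px\n",
              object@sx, object@sy))
})

setMethod("show", "MotionMetrics", function(object) {
  cat("MotionMetrics (one procedure)\n")
  cat(sprintf("  N = %d frames at %g fps; T = %.3f s\n",
              object@nFrames, object@frameRate, object@totalTime))
  cat(sprintf("  D = %.3f cm; D-bar = %.4f cm/frame; S-bar = %.3f cm/s\n",
              object@pathLength, object@meanStep, object@meanSpeed))
  cat(sprintf("  E = %d extreme steps (d_th = %g cm), %d below; %.1f cm/min\n",
              object@extremeCount, object@threshold, object@belowCount,
              object@pathPerMinute))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison [%s]: medians %.4g vs %.4g (n = %d vs %d), U = %g, p = %.4g%s\n",
    object@metricName, object@medianA, object@medianB, object@nA,
    object@nB, object@statistic, object@pValue,
    if (object@significant) " *" else ""))
})

setMethod("show", "BiasReport", function(object) {
  cat(sprintf(
    "BiasReport: %d pairs, median relative difference %.4g, %d outliers (>|%g|)\n",
    nrow(object@table), object@medianRelDiff, sum(object@table$outlier),
    object@outlierThreshold))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d frames, true D = %.3f cm, %d occluded frames\n",
    nrow(object@cmTrajectory), object@trueMetrics@pathLength,
    length(object@occludedFrames)))
})
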