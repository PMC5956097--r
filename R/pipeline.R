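# End-to-end orchestration: track -> calibrate -> scale -> metrics ->
# compare, with file-based inputs/outputs and a JSON run manifest so any
# run can be reproduced exactly. A thin command-line wrapper over these
# functions ships in inst/scripts/lapmotion.

.manifest <- function(outDir, config, inputs = character()) {
  man <- list(
    package = "lapMotion",
    version = as.character(utils::packageVersion("lapMotion")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the tracking stage and write trajectory + calibration CSVs
#'
#' @param video a \linkS4class{FrameSource} or a directory of PNG frames.
#' @param seed joint seed \code{c(x, y)} in pixels (frame 1).
#' @param lineSeeds the 4 calibration endpoints (8-vector or 4 x 2 matrix).
#' @param realLength1,realLength2 real line lengths, cm.
#' @param frameRate frames per second (used when \code{video} is a path).
#' @param config a \linkS4class{TrackerConfig}.
#' @param corrections optional joint corrections: data.frame or CSV path
#'   with columns \code{frame}, \code{x_px}, \code{y_px}.
#' @param outDir output directory; receives \code{trajectory.csv},
#'   \code{calibration.csv} and \code{manifest.json}.
#' @return invisibly, list with the \linkS4class{RawTrajectory} and
#'   \linkS4class{CalibrationTrack}.
#' @export
runTrack <- function(video, seed, lineSeeds, realLength1, realLength2,
                     frameRate = 25, config = trackerConfig(),
                     corrections = NULL, outDir = ".") {
  if (is.null(realLength1) || is.null(realLength2) ||
      !is.finite(realLength1) || !is.finite(realLength2) ||
      realLength1 <= 0 || realLength2 <= 0)
    .err("config", "real calibration line lengths (cm) are required")
  inputs <- character()
  if (is.character(video)) {
    inputs <- c(inputs, list.files(video, full.names = TRUE))
    video <- frameSource(video, frameRate)
  }
  if (is.character(corrections)) {
    inputs <- c(inputs, corrections)
    corrections <- utils::read.csv(corrections)
    names(corrections)[1:3] <- c("frame", "x", "y")
  }
  traj <- trackPoint(video, seed, config, corrections)
  calib <- trackLines(video, lineSeeds, realLength1, realLength2, config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeTrajectoryCSV(traj, file.path(outDir, "trajectory.csv"))
  writeCalibrationCSV(calib, file.path(outDir, "calibration.csv"))
  .manifest(outDir,
            list(stage = "track", seed = as.numeric(seed),
                 line_seeds = as.numeric(lineSeeds),
                 real_length1_cm = realLength1,
                 real_length2_cm = realLength2,
                 frame_rate = frameRate,
                 template_radius = config@templateRadius,
                 search_radius = config@searchRadius,
                 confidence_floor = config@confidenceFloor,
                 mode = config@mode),
            inputs)
  invisible(list(trajectory = traj, calibration = calib))
}

#' Chain calibration, scaling and metrics for one trajectory
#'
#' @param trajectory a \linkS4class{RawTrajectory} or trajectory CSV path.
#' @param calibration a \linkS4class{CalibrationTrack} or calibration CSV
#'   path.
#' @param realLength1,realLength2 real line lengths, cm (needed when
#'   \code{calibration} is a path).
#' @param frameRate frames per second (needed for CSV inputs).
#' @param scalingMode \code{"average"} or \code{"per_frame"}.
#' @param config a \linkS4class{MetricsConfig}.
#' @param out optional output path for the metrics (.csv or .json).
#' @return the \linkS4class{MotionMetrics}.
#' @export
runMetrics <- function(trajectory, calibration,
                       realLength1 = NULL, realLength2 = NULL,
                       frameRate = 25, scalingMode = "average",
                       config = metricsConfig(), out = NULL) {
  if (is.character(trajectory))
    trajectory <- readTrajectoryCSV(trajectory, frameRate)
  if (is.character(calibration)) {
    if (is.null(realLength1) || is.null(realLength2))
      .err("config", "real line lengths are required with a calibration CSV")
    calibration <- readCalibrationCSV(calibration, realLength1, realLength2,
                                      frameRate)
  }
  scales <- perFrameScales(calibration)
  scaled <- applyScaling(trajectory, scales, scalingMode)
  m <- computeMetrics(scaled, config)
  if (!is.null(out)) writeMetrics(m, out)
  m
}

#' Compare all metrics between the two groups of a cohort table
#'
#' @param metricsTable data.frame (or CSV path) with a \code{group} column
#'   holding exactly two labels plus per-procedure metric columns.
#' @param metrics which metric columns to compare.
#' @param alpha significance level.
#' @param out optional output path (.csv or .json) for the comparison
#'   table.
#' @return data.frame with one row per metric: medians, U, p-value and
#'   significance flag (group A = first label in sorted order).
#' @export
runCompare <- function(metricsTable,
                       metrics = c("path_length_cm", "mean_step_cm",
                                   "mean_speed_cm_s", "extreme_count",
                                   "path_per_minute_cm"),
                       alpha = 0.05, out = NULL) {
  if (is.character(metricsTable))
    metricsTable <- utils::read.csv(metricsTable)
  if (is.null(metricsTable$group))
    .err("parse", "metrics table is missing the 'group' column")
  labs <- sort(unique(as.character(metricsTable$group)))
  if (length(labs) != 2L)
    .err("config", sprintf("need exactly 2 groups, found %d", length(labs)))
  metrics <- intersect(metrics, names(metricsTable))
  rows <- lapply(metrics, function(m) {
    cmp <- compareGroups(metricsTable[[m]][metricsTable$group == labs[1L]],
                         metricsTable[[m]][metricsTable$group == labs[2L]],
                         metricName = m, alpha = alpha)
    cbind(as.data.frame(cmp),
          data.frame(group_a = labs[1L], group_b = labs[2L]))
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    if (grepl("\\.json$", out, ignore.case = TRUE))
      jsonlite::write_json(res, out, dataframe = "rows", digits = NA)
    else
      utils::write.csv(res, out, row.names = FALSE)
  }
  res
}
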