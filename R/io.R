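# Plain-text / PNG I/O. CSV schemas:
#   trajectory:   frame,x_px,y_px,status,confidence   (gap rows empty)
#   corrections:  frame,x_px,y_px
#   calibration:  frame,l1x1,l1y1,l1x2,l1y2,l2x1,l2y1,l2x2,l2y2
#   scaled:       frame,x_cm,y_cm,status
#   metrics:      one row per procedure with all MotionMetrics fields

# Rec. 601 luma conversion for RGB(A) arrays; grayscale passes through
.toIntensity <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) return(img[, , 1L])
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  }
  .err("io", "frames must be matrices or RGB(A) arrays")
}

#' Read a directory of PNG frames
#'
#' Files are read in lexicographic order (zero-pad frame numbers); RGB
#' frames are converted to intensity with Rec. 601 luma weights.
#'
#' @param dir directory containing \code{*.png} files.
#' @return list of grayscale matrices.
#' @export
readFramesPNG <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 2L)
    .err("io", sprintf("need at least 2 PNG frames in '%s'", dir))
  lapply(files, function(f) .toIntensity(png::readPNG(f)))
}

#' Write a FrameSource as numbered PNG frames
#'
#' @param frames a \linkS4class{FrameSource}.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
writeFramesPNG <- function(frames, dir) {
  stopifnot(is(frames, "FrameSource"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%05d.png", seq_along(frames@frames)))
  for (i in seq_along(paths)) png::writePNG(frames@frames[[i]], paths[i])
  invisible(paths)
}

#' Write / read a raw pixel trajectory CSV
#'
#' @param traj a \linkS4class{RawTrajectory}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  stopifnot(is(traj, "RawTrajectory"))
  p <- traj@points
  out <- data.frame(frame = p$frame, x_px = p$x, y_px = p$y,
                    status = p$status, confidence = p$confidence)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @param path CSV path to read.
#' @param frameRate frames per second of the source video.
#' @return a \linkS4class{RawTrajectory}.
#' @export
readTrajectoryCSV <- function(path, frameRate) {
  d <- utils::read.csv(path)
  need <- c("frame", "x_px", "y_px", "status")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .err("parse", paste("trajectory CSV is missing column(s):",
                        paste(miss, collapse = ", ")))
  if (is.null(d$confidence)) d$confidence <- NA_real_
  .rawTrajectory(
    data.frame(frame = d$frame, x = as.numeric(d$x_px),
               y = as.numeric(d$y_px), status = d$status,
               confidence = as.numeric(d$confidence)),
    frameRate)
}

#' Write / read a calibration-line CSV
#'
#' Invalid frames (any endpoint lost) are written with empty coordinate
#' cells and recovered as invalid on read.
#'
#' @param track a \linkS4class{CalibrationTrack}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeCalibrationCSV <- function(track, path) {
  stopifnot(is(track, "CalibrationTrack"))
  e <- track@endpoints
  out <- e[, c("frame", "l1x1", "l1y1", "l1x2", "l1y2",
               "l2x1", "l2y1", "l2x2", "l2y2")]
  out[!e$valid, -1L] <- NA
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCalibrationCSV
#' @param path CSV path to read.
#' @param realLength1,realLength2 real line lengths, cm.
#' @param frameRate frames per second.
#' @return a \linkS4class{CalibrationTrack}.
#' @export
readCalibrationCSV <- function(path, realLength1, realLength2,
                               frameRate = 25) {
  d <- utils::read.csv(path)
  need <- c("frame", "l1x1", "l1y1", "l1x2", "l1y2",
            "l2x1", "l2y1", "l2x2", "l2y2")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .err("parse", paste("calibration CSV is missing column(s):",
                        paste(miss, collapse = ", ")))
  d$valid <- stats::complete.cases(d[, need[-1L]])
  new("CalibrationTrack", endpoints = d,
      realLength1 = as.numeric(realLength1),
      realLength2 = as.numeric(realLength2),
      frameRate = as.numeric(frameRate))
}

#' Write a scaled (cm) trajectory CSV
#'
#' @param traj a \linkS4class{ScaledTrajectory}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeScaledCSV <- function(traj, path) {
  stopifnot(is(traj, "ScaledTrajectory"))
  p <- traj@points
  utils::write.csv(
    data.frame(frame = p$frame, x_cm = p$x, y_cm = p$y, status = p$status),
    path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write motion metrics to CSV or JSON
#'
#' @param metrics a \linkS4class{MotionMetrics} or a data.frame of
#'   per-procedure metric rows (batch mode).
#' @param path output path; format chosen by extension (.json vs .csv).
#' @return invisibly, \code{path}.
#' @export
writeMetrics <- function(metrics, path) {
  d <- if (is(metrics, "MotionMetrics")) as.data.frame(metrics) else
    as.data.frame(metrics)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(d, path, dataframe = "rows", auto_unbox = FALSE,
                         digits = NA)
  else
    utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
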