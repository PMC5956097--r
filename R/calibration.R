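# Pixel-to-centimetre calibration from two perpendicular reference lines.
#
# Each reference line i has a pixel vector (dx_i, dy_i) and a known real
# length L_i (cm). Axis scales (sx, sy) in cm/px must give each scaled
# line its real length:
#
#     sx^2 * dx_i^2 + sy^2 * dy_i^2 = L_i^2,   i = 1, 2
#
# which is linear in (sx^2, sy^2). Two lines in general position (in
# practice, perpendicular lines along the instrument's second segment)
# make the 2x2 system non-singular; anisotropy between sx and sy absorbs
# the in-plane foreshortening of the instrument's out-of-plane tilt.

#' Solve the two-line axis-scale system
#'
#' @param line1,line2 pixel vectors (dx, dy) of the two reference lines.
#' @param L1,L2 their known real lengths, cm.
#' @return a \linkS4class{ScaleFactors} with the cm-per-pixel factors.
#' @examples
#' solveAxisScales(c(10, 0), c(0, 20), 1, 1)  # sx = 0.1, sy = 0.05
#' @export
solveAxisScales <- function(line1, line2, L1, L2) {
  if (sum(line1^2) == 0 || sum(line2^2) == 0)
    .err("degenerate_calibration", "line vectors must be non-zero")
  A <- rbind(c(line1[1L]^2, line1[2L]^2),
             c(line2[1L]^2, line2[2L]^2))
  b <- c(L1^2, L2^2)
  det <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
  if (abs(det) < .Machine$double.eps * max(abs(A))^2 * 4)
    .err("degenerate_calibration",
         "the two lines constrain the same axis combination (singular system)")
  s2 <- solve(A, b)
  if (any(s2 <= 0))
    .err("inconsistent_calibration",
         "the line geometry admits no positive axis scales")
  scaleFactors(sqrt(s2[1L]), sqrt(s2[2L]))
}

#' Per-frame axis scales from a calibration track
#'
#' Applies \code{\link{solveAxisScales}} on every valid frame. Frames with
#' a lost endpoint inherit the nearest preceding valid frame's scales;
#' leading invalid frames fall back to the first valid frame. This lets
#' clips filmed at varying camera distance be expressed in a common cm
#' scale.
#'
#' @param track a \linkS4class{CalibrationTrack}.
#' @return data.frame with columns \code{frame}, \code{sx}, \code{sy}
#'   (cm/px), one row per frame.
#' @export
perFrameScales <- function(track) {
  stopifnot(is(track, "CalibrationTrack"))
  e <- track@endpoints
  if (!any(e$valid))
    .err("calibration_unavailable", "no frame has all four endpoints tracked")
  N <- nrow(e)
  sx <- rep(NA_real_, N); sy <- rep(NA_real_, N)
  for (i in which(e$valid)) {
    s <- solveAxisScales(c(e$l1x2[i] - e$l1x1[i], e$l1y2[i] - e$l1y1[i]),
                         c(e$l2x2[i] - e$l2x1[i], e$l2y2[i] - e$l2y1[i]),
                         track@realLength1, track@realLength2)
    sx[i] <- s@sx; sy[i] <- s@sy
  }
  firstValid <- which(e$valid)[1L]
  if (firstValid > 1L) {
    sx[seq_len(firstValid - 1L)] <- sx[firstValid]
    sy[seq_len(firstValid - 1L)] <- sy[firstValid]
  }
  for (i in seq_len(N)) {        # carry the last valid scale forward
    if (is.na(sx[i])) { sx[i] <- sx[i - 1L]; sy[i] <- sy[i - 1L] }
  }
  data.frame(frame = e$frame, sx = sx, sy = sy)
}

#' Convert a pixel trajectory to centimetres
#'
#' In \code{"average"} mode (the default) each axis factor is averaged
#' over the frames where calibration was valid and applied uniformly; in
#' \code{"per_frame"} mode each frame uses its own factors, compensating
#' camera-distance changes frame by frame.
#'
#' @param raw a \linkS4class{RawTrajectory}.
#' @param scales either a \linkS4class{ScaleFactors} (constant scaling) or
#'   a per-frame data.frame from \code{\link{perFrameScales}} (must have
#'   one row per frame of \code{raw}).
#' @param mode \code{"average"} or \code{"per_frame"}.
#' @return a \linkS4class{ScaledTrajectory} in cm, with the gap structure
#'   of \code{raw}.
#' @export
applyScaling <- function(raw, scales, mode = c("average", "per_frame")) {
  stopifnot(is(raw, "RawTrajectory"))
  mode <- match.arg(mode)
  p <- raw@points
  N <- nrow(p)
  if (is(scales, "ScaleFactors")) {
    sx <- rep(scales@sx, N); sy <- rep(scales@sy, N)
  } else {
    scales <- as.data.frame(scales)
    if (nrow(scales) != N)
      .err("contract", sprintf(
        "scale sequence has %d rows but the trajectory has %d frames",
        nrow(scales), N))
    sx <- scales$sx; sy <- scales$sy
  }
  if (mode == "average") {
    sx <- rep(mean(sx), N)
    sy <- rep(mean(sy), N)
  }
  .scaledTrajectory(
    data.frame(frame = p$frame, x = sx * p$x, y = sy * p$y,
               status = p$status),
    raw@frameRate)
}
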