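# Kinematic criteria for one tracked procedure.
#
# With scaled coordinates (x'_n, y'_n), n = 1..N, at f frames/second:
#   d_{n+1} = sqrt((x'_{n+1} - x'_n)^2 + (y'_{n+1} - y'_n)^2)   [cm]
#   T = N / f                                                   [s]
#   D = sum_{n=1}^{N-1} d_{n+1}                                 [cm]
#   D-bar = D / (N - 1)                                         [cm/frame]
#   S-bar = D / T                                               [cm/s]
#   E = #{ d_{n+1} >= d_th }, plus the complementary below count.
# Gap runs (occluded/out-of-view frames bridged by a relocated point) are
# imputed by the configured policy before the sums are taken.

#' Inter-frame displacements of a scaled trajectory
#'
#' Computes the Euclidean distance between consecutive tracked frames.
#' A gap of k missing frames bridged by the last tracked point A and the
#' relocated point B contributes, under policy
#' \code{"interpolate_uniform"}, k+1 equal steps of |B-A|/(k+1) (the
#' movement is assumed uniform across the untracked span); under
#' \code{"exclude"}, a single step |B-A| counted once. Leading or
#' trailing gap runs have no bridging point and contribute nothing.
#'
#' @param traj a \linkS4class{ScaledTrajectory}.
#' @param gapPolicy \code{"interpolate_uniform"} or \code{"exclude"}.
#' @return numeric vector of step distances in cm.
#' @export
frameDistances <- function(traj,
                           gapPolicy = c("interpolate_uniform", "exclude")) {
  stopifnot(is(traj, "ScaledTrajectory"))
  gapPolicy <- match.arg(gapPolicy)
  p <- traj@points
  if (nrow(p) < 2L)
    .err("insufficient_frames", "at least 2 frames are needed")
  ok <- which(p$status != "gap")
  if (length(ok) < 2L)
    .err("no_data", "fewer than 2 tracked frames between first and last")
  d <- numeric(0)
  for (j in seq_len(length(ok) - 1L)) {
    a <- ok[j]; b <- ok[j + 1L]
    span <- sqrt((p$x[b] - p$x[a])^2 + (p$y[b] - p$y[a])^2)
    k <- b - a - 1L                      # missing frames in between
    if (k == 0L) {
      d <- c(d, span)
    } else if (gapPolicy == "interpolate_uniform") {
      d <- c(d, rep(span / (k + 1L), k + 1L))
    } else {
      d <- c(d, span)
    }
  }
  d
}

#' Compute the motion metrics of one procedure
#'
#' @param traj a \linkS4class{ScaledTrajectory} in cm.
#' @param config a \linkS4class{MetricsConfig}; its threshold d_th
#'   (cm/frame) splits steps into extreme (d >= d_th, or > with
#'   \code{strictInequality}) and below-threshold counts.
#' @return a \linkS4class{MotionMetrics}.
#' @examples
#' p <- data.frame(frame = 1:3, x = c(0, 3, 3), y = c(0, 4, 5),
#'                 status = "auto")
#' m <- computeMetrics(new("ScaledTrajectory", points = p, frameRate = 25))
#' m
#' @export
computeMetrics <- function(traj, config = metricsConfig()) {
  stopifnot(is(traj, "ScaledTrajectory"), is(config, "MetricsConfig"))
  p <- traj@points
  N <- nrow(p)
  if (N < 2L)
    .err("insufficient_frames", "metrics need at least 2 frames")
  f <- traj@frameRate
  d <- frameDistances(traj, config@gapPolicy)
  D <- sum(d)
  T <- N / f
  extreme <- if (config@strictInequality) d > config@extremeThreshold
             else d >= config@extremeThreshold
  new("MotionMetrics",
      nFrames = N, frameRate = f, totalTime = T, pathLength = D,
      meanStep = D / (N - 1L), meanSpeed = D / T,
      extremeCount = sum(extreme), belowCount = sum(!extreme),
      pathPerMinute = 60 * D / T, threshold = config@extremeThreshold)
}
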