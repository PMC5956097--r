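# Template-matching point tracker.
#
# Frames are grayscale matrices indexed [row, col] = [y, x], origin at the
# top-left, 1-based integer pixel coordinates. Matching is normalized
# cross-correlation (NCC) at integer pixel resolution: the template is the
# square patch of side 2 * templateRadius + 1 around the last accepted
# location, scored against every candidate centre in the search window.
# Patches extending beyond the frame are zero-padded.

# patch of side 2r+1 centred at integer (x, y); zero outside the frame
.extractPatch <- function(frame, x, y, r) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(0, 2L * r + 1L, 2L * r + 1L)
  ys <- max(1L, y - r):min(h, y + r)
  xs <- max(1L, x - r):min(w, x + r)
  if (length(ys) && length(xs))
    out[ys - (y - r) + 1L, xs - (x - r) + 1L] <- frame[ys, xs]
  out
}

# sum of M over the (2r+1)x(2r+1) window centred at each cell (zero
# outside M), via an integral image
.boxSum <- function(M, r) {
  m1 <- nrow(M); m2 <- ncol(M); w <- 2L * r + 1L
  P <- matrix(0, m1 + 2L * r, m2 + 2L * r)
  P[(r + 1L):(r + m1), (r + 1L):(r + m2)] <- M
  cs <- apply(P, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  I <- matrix(0, nrow(cs) + 1L, ncol(cs) + 1L)
  I[-1L, -1L] <- cs
  i <- seq_len(m1); j <- seq_len(m2)
  I[i + w, j + w, drop = FALSE] - I[i, j + w, drop = FALSE] -
    I[i + w, j, drop = FALSE] + I[i, j, drop = FALSE]
}

# NCC score map of one template over candidate centres x0..x1, y0..y1 of a
# frame (zero-padded at borders). The numerator is a circular FFT
# cross-correlation on a region large enough that no candidate wraps; the
# denominator comes from box sums of the region and its square. Flat
# patches or a flat template score 0.
.nccMap <- function(frame, template, x0, x1, y0, y1) {
  r <- (nrow(template) - 1L) %/% 2L
  h <- nrow(frame); w <- ncol(frame)
  # round the region up to FFT-friendly sizes; the extra zero rows/cols
  # only add candidates that are never extracted
  m1 <- stats::nextn((y1 - y0 + 1L) + 2L * r, c(2L, 3L, 5L))
  m2 <- stats::nextn((x1 - x0 + 1L) + 2L * r, c(2L, 3L, 5L))
  S <- matrix(0, m1, m2)
  ys <- max(1L, y0 - r):min(h, y1 + r)
  xs <- max(1L, x0 - r):min(w, x1 + r)
  S[ys - (y0 - r) + 1L, xs - (x0 - r) + 1L] <- frame[ys, xs]

  tc <- template - mean(template)
  denT <- sqrt(sum(tc * tc))
  Tp <- matrix(0, m1, m2)
  Tp[((-r:r) %% m1) + 1L, ((-r:r) %% m2) + 1L] <- tc
  num <- Re(stats::fft(stats::fft(S) * Conj(stats::fft(Tp)),
                       inverse = TRUE)) / (m1 * m2)
  npix <- (2L * r + 1L)^2
  S1 <- .boxSum(S, r)
  S2 <- .boxSum(S * S, r)
  den <- sqrt(pmax(S2 - S1 * S1 / npix, 0)) * denT
  sc <- num / den
  sc[!is.finite(sc) | den <= 1e-12] <- 0
  sc[sc > 1] <- 1; sc[sc < -1] <- -1
  # rows y0..y1, cols x0..x1 of the candidate grid
  sc[(r + 1L):(r + y1 - y0 + 1L), (r + 1L):(r + x1 - x0 + 1L),
     drop = FALSE]
}

# pick the best candidate from a score map: maximal score (scores within
# 1e-9 count as tied), ties broken by smallest displacement from
# (prevX, prevY), then row-major order (smallest y, then smallest x)
.pickBest <- function(sc, x0, y0, prevX, prevY) {
  best <- max(sc)
  tie <- which(sc >= best - 1e-9)
  ty <- ((tie - 1L) %% nrow(sc)) + y0
  tx <- ((tie - 1L) %/% nrow(sc)) + x0
  d2 <- (tx - prevX)^2 + (ty - prevY)^2
  keep <- which(d2 == min(d2))
  if (length(keep) > 1L) {
    ord <- order(ty[keep], tx[keep])
    keep <- keep[ord[1L]]
  }
  i <- keep[1L]
  list(x = tx[i], y = ty[i], score = sc[tie[i]])
}

# search around (prevX, prevY) within searchRadius
.localSearch <- function(frame, template, prevX, prevY, cfg) {
  sr <- cfg@searchRadius
  x0 <- max(1L, prevX - sr); x1 <- min(ncol(frame), prevX + sr)
  y0 <- max(1L, prevY - sr); y1 <- min(nrow(frame), prevY + sr)
  sc <- .nccMap(frame, template, x0, x1, y0, y1)
  .pickBest(sc, x0, y0, prevX, prevY)
}

# global search over every pixel of the frame
.globalSearch <- function(frame, template, prevX, prevY, cfg) {
  sc <- .nccMap(frame, template, 1L, ncol(frame), 1L, nrow(frame))
  .pickBest(sc, 1L, 1L, prevX, prevY)
}

.inBounds <- function(x, y, frame) {
  x >= 1 && x <= ncol(frame) && y >= 1 && y <= nrow(frame)
}

# normalise a corrections argument to a data.frame(frame, x, y)
.asCorrections <- function(corrections) {
  if (is.null(corrections))
    return(data.frame(frame = integer(), x = numeric(), y = numeric()))
  corrections <- as.data.frame(corrections)
  names(corrections)[1:3] <- c("frame", "x", "y")
  corrections$frame <- as.integer(corrections$frame)
  corrections
}

#' Track a seeded point through a frame sequence
#'
#' Semi-automatic frame-to-frame tracking of a single point (typically the
#' instrument's first joint). The template patch around the last accepted
#' location is matched by normalized cross-correlation within the search
#' window of the next frame; the template is refreshed after every
#' accepted frame (unless \code{refreshTemplate = FALSE}). Frames whose
#' best score falls below \code{confidenceFloor} are marked \code{gap}
#' until either the match recovers or a manual correction relocates the
#' point. In fully-automatic mode corrections are ignored and a lost point
#' is re-acquired as the global best match over the whole frame.
#'
#' @param frames a \linkS4class{FrameSource}.
#' @param seed the pixel location of the point in frame 1: a length-2
#'   numeric \code{c(x, y)}.
#' @param config a \linkS4class{TrackerConfig}.
#' @param corrections optional data.frame with columns \code{frame},
#'   \code{x}, \code{y}: frames listed here take the given location with
#'   status \code{manual} (ignored in fully-automatic mode).
#' @return a \linkS4class{RawTrajectory} with one point per frame.
#' @examples
#' fs <- frameSource(replicate(5, {
#'   f <- matrix(0, 64, 64); f[30:34, 40:44] <- 1; f
#' }, simplify = FALSE), frameRate = 25)
#' tr <- trackPoint(fs, seed = c(42, 32))
#' head(as.data.frame(tr))
#' @export
trackPoint <- function(frames, seed, config = trackerConfig(),
                       corrections = NULL) {
  stopifnot(is(frames, "FrameSource"), is(config, "TrackerConfig"))
  flist <- frames@frames
  N <- length(flist)
  seedX <- as.integer(round(seed[[1L]]))
  seedY <- as.integer(round(seed[[2L]]))
  if (!.inBounds(seedX, seedY, flist[[1L]]))
    .err("invalid_seed",
         sprintf("seed (%d, %d) lies outside the %d x %d frame",
                 seedX, seedY, ncol(flist[[1L]]), nrow(flist[[1L]])))
  corr <- .asCorrections(corrections)
  if (nrow(corr) && (any(corr$frame < 1L) || any(corr$frame > N)))
    .err("invalid_correction", "correction frame indices must lie in 1..N")
  auto_mode <- config@mode == "fully_automatic"

  x <- rep(NA_real_, N); y <- rep(NA_real_, N)
  status <- rep("gap", N); conf <- rep(NA_real_, N)

  lastX <- seedX; lastY <- seedY
  x[1L] <- seedX; y[1L] <- seedY; status[1L] <- "auto"; conf[1L] <- 1
  template <- .extractPatch(flist[[1L]], seedX, seedY, config@templateRadius)
  seedTemplate <- template

  for (n in 2L:N) {
    fr <- flist[[n]]
    ci <- if (!auto_mode) match(n, corr$frame) else NA_integer_
    if (!is.na(ci)) {
      cx <- as.integer(round(corr$x[ci])); cy <- as.integer(round(corr$y[ci]))
      if (!.inBounds(cx, cy, fr))
        .err("invalid_correction",
             sprintf("correction at frame %d lies outside the frame", n))
      x[n] <- cx; y[n] <- cy; status[n] <- "manual"
      lastX <- cx; lastY <- cy
      if (config@refreshTemplate)
        template <- .extractPatch(fr, cx, cy, config@templateRadius)
      next
    }
    hit <- .localSearch(fr, template, lastX, lastY, config)
    if (hit$score < config@confidenceFloor && auto_mode)
      hit <- .globalSearch(fr, template, lastX, lastY, config)
    if (hit$score >= config@confidenceFloor || auto_mode) {
      x[n] <- hit$x; y[n] <- hit$y; status[n] <- "auto"; conf[n] <- hit$score
      lastX <- hit$x; lastY <- hit$y
      # refresh only on confident matches: a low-confidence global
      # re-acquisition must not overwrite the template with clutter
      if (config@refreshTemplate && hit$score >= config@confidenceFloor)
        template <- .extractPatch(fr, hit$x, hit$y, config@templateRadius)
    }
    # else: status stays "gap"; template and last location are kept so the
    # point can be re-acquired when the match recovers
  }

  if (N > 1L && all(status[-1L] == "gap"))
    .err("tracking_failed", "the point was lost on every frame after the seed")

  .rawTrajectory(
    data.frame(frame = seq_len(N), x = x, y = y, status = status,
               confidence = conf),
    frames@frameRate)
}

#' Track the endpoints of the two calibration lines
#'
#' Tracks the four line endpoints independently with the same NCC tracker
#' as \code{\link{trackPoint}} and assembles the per-frame line endpoints.
#' A frame is valid only when all four endpoints were matched; frames with
#' any lost endpoint are flagged invalid (gap).
#'
#' @param frames a \linkS4class{FrameSource}.
#' @param seedEndpoints the four endpoints in frame 1, as an 8-vector
#'   \code{c(l1x1, l1y1, l1x2, l1y2, l2x1, l2y1, l2x2, l2y2)} or a 4 x 2
#'   matrix (rows in that order).
#' @param realLength1,realLength2 known real lengths of the two lines, cm.
#' @param config a \linkS4class{TrackerConfig}.
#' @param corrections optional list of up to four correction data.frames
#'   (one per endpoint, in seeding order; \code{NULL} entries allowed).
#' @return a \linkS4class{CalibrationTrack}.
#' @export
trackLines <- function(frames, seedEndpoints, realLength1, realLength2,
                       config = trackerConfig(), corrections = NULL) {
  stopifnot(is(frames, "FrameSource"))
  ep <- if (is.matrix(seedEndpoints)) seedEndpoints else
    matrix(as.numeric(seedEndpoints), ncol = 2L, byrow = TRUE)
  if (nrow(ep) != 4L)
    .err("invalid_calibration", "seedEndpoints must give 4 points (x, y)")
  v1 <- ep[2L, ] - ep[1L, ]; v2 <- ep[4L, ] - ep[3L, ]
  if (sum(v1^2) == 0 || sum(v2^2) == 0)
    .err("invalid_calibration", "degenerate seed segment (zero length)")
  ang <- acos(abs(sum(v1 * v2)) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  if (ang < 80)
    .warn("nonperpendicular_seed",
          sprintf("seed lines meet at %.1f deg from perpendicular; %s",
                  90 - ang, "proceeding (the solve only needs non-singularity)"))
  if (realLength1 <= 0 || realLength2 <= 0)
    .err("invalid_calibration", "real line lengths must be positive")

  tracks <- lapply(1:4, function(i) {
    co <- if (!is.null(corrections) && length(corrections) >= i)
      corrections[[i]] else NULL
    trackPoint(frames, ep[i, ], config, co)@points
  })
  N <- frameCount(frames)
  valid <- Reduce(`&`, lapply(tracks, function(t) t$status != "gap"))
  e <- data.frame(frame = seq_len(N),
                  l1x1 = tracks[[1L]]$x, l1y1 = tracks[[1L]]$y,
                  l1x2 = tracks[[2L]]$x, l1y2 = tracks[[2L]]$y,
                  l2x1 = tracks[[3L]]$x, l2y1 = tracks[[3L]]$y,
                  l2x2 = tracks[[4L]]$x, l2y2 = tracks[[4L]]$y,
                  valid = valid)
  new("CalibrationTrack", endpoints = e,
      realLength1 = as.numeric(realLength1),
      realLength2 = as.numeric(realLength2),
      frameRate = frames@frameRate)
}
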