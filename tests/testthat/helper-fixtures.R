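# Fixtures built in code: tiny frame sequences with exactly known ground
# truth, plus independent brute-force oracles.

# frames with a bright 5x5 marker at integer positions (x[n], y[n]) on a
# black background; independent of the package's renderer
markerFrames <- function(xs, ys, w = 120L, h = 100L, bg = 0, fg = 1,
                         blank = integer(0)) {
  lapply(seq_along(xs), function(n) {
    f <- matrix(bg, h, w)
    if (!(n %in% blank)) {
      cx <- xs[n]; cy <- ys[n]
      f[(cy - 2):(cy + 2), (cx - 2):(cx + 2)] <- fg
    }
    f
  })
}

# a ScaledTrajectory straight from coordinates
cmTraj <- function(x, y, f = 25, status = rep("auto", length(x))) {
  new("ScaledTrajectory",
      points = data.frame(frame = seq_along(x), x = ifelse(status == "gap", NA, x),
                          y = ifelse(status == "gap", NA, y), status = status),
      frameRate = f)
}

# brute-force metrics oracle: plain re-computation from first principles,
# no shared code with computeMetrics beyond arithmetic
oracleMetrics <- function(x, y, f, dth, status = rep("auto", length(x)),
                          gapPolicy = "interpolate_uniform") {
  N <- length(x)
  ok <- which(status != "gap")
  d <- c()
  for (j in seq_len(length(ok) - 1)) {
    a <- ok[j]; b <- ok[j + 1]
    span <- sqrt((x[b] - x[a])^2 + (y[b] - y[a])^2)
    k <- b - a - 1
    d <- if (k == 0) c(d, span)
         else if (gapPolicy == "interpolate_uniform")
           c(d, rep(span / (k + 1), k + 1))
         else c(d, span)
  }
  D <- sum(d); T <- N / f
  list(T = T, D = D, Dbar = D / (N - 1), Sbar = D / T,
       E = sum(d >= dth), below = sum(d < dth), ppm = 60 * D / T)
}

# exact two-sided rank-sum p-value by full enumeration of all
# choose(nA+nB, nA) group assignments (U statistic for group A)
enumRankSum <- function(a, b) {
  nA <- length(a); nB <- length(b)
  all <- c(a, b)
  U <- function(idx) {
    ra <- rank(all)[idx]
    sum(ra) - nA * (nA + 1) / 2
  }
  obs <- U(seq_len(nA))
  combs <- utils::combn(nA + nB, nA)
  us <- apply(combs, 2, U)
  mu <- nA * nB / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# a small rendered clip shared by several tests (built once per file)
.clipCache <- new.env()
renderedClip <- function(frames = 120L, noiseSd = 0, seed = 11,
                         occlude = integer(0), decoyAt = NULL) {
  key <- paste(frames, noiseSd, seed, paste(occlude, collapse = "-"),
               paste(decoyAt, collapse = "-"), sep = "_")
  if (!is.null(.clipCache[[key]])) return(.clipCache[[key]])
  prof <- skillProfile(stepScale = 0.12, smoothness = 0.8, jerkRate = 0.03,
                       jerkMagnitude = 0.4, durationFrames = frames)
  gt <- generateTrajectory(prof, seed = seed, start = c(3.2, 2.4),
                           bounds = c(1.8, 4.6, 1.4, 3.4),
                           config = metricsConfig(0.25))
  rv <- renderVideo(gt$trajectory, cameraProfile(noiseSd = noiseSd),
                    seed = seed, occludeFrames = occlude, decoyAt = decoyAt,
                    config = metricsConfig(0.25))
  rv$generated <- gt
  .clipCache[[key]] <- rv
  rv
}

jointSeed <- function(rv) round(as.numeric(rv$truth@pixelTrajectory[1, c("x", "y")]))
lineSeeds <- function(rv) round(as.numeric(rv$truth@lineEndpoints[1, -1]))
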