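# lapMotion

Software-only video motion tracking for objective surgical-skill
assessment.

Motion tracking discriminates well between expert and novice surgical
performance, but most tracking systems need extra hardware in the
operating room. lapMotion works from the recorded video alone: it
tracks one well-chosen point on the instrument (the first joint)
through the frames, converts the pixel trajectory to centimetres using
two perpendicular reference lines of known real length drawn along the
instrument's second segment, computes kinematic skill criteria, and
compares cohorts with rank-based statistics. It is aimed at surgical
educators and researchers analysing laparoscopic recordings, and ships
a ground-truthed synthetic video generator so the whole pipeline can be
validated without any clinical data.

## The method

**Tracking.** A user-seeded point is followed frame to frame by
normalized cross-correlation template matching (template radius 10 px,
search radius 25 px, confidence floor 0.5 by default). Frames whose
best match falls below the floor become *gaps*; a corrections table
relocates the point manually (semi-automatic mode), or the tracker
re-acquires the global best match automatically (fully-automatic mode).

**Calibration.** With two perpendicular lines of known lengths
L₁, L₂ (cm) and per-frame pixel vectors (Δxᵢ, Δyᵢ), the cm-per-pixel
axis scales solve

  s_x² Δxᵢ² + s_y² Δyᵢ² = Lᵢ²,  i = 1, 2,

a linear system in (s_x², s_y²). This compensates camera distance and
first-order out-of-plane foreshortening, making recordings taken at
different distances comparable.

**Metrics.** For scaled coordinates (x′ₙ, y′ₙ), n = 1..N at f fps:
step distances d = √(Δx′² + Δy′²), total time T = N/f, path length
D = Σd, average movement D̄ = D/(N−1), average speed S̄ = D/T, the
count E of extreme movements (d ≥ d_th, default 1 cm/frame) and path
length per minute. Occlusion gaps are bridged by uniform interpolation
(default) or counted as a single excluded step.

**Statistics.** Two-sided Mann–Whitney/Wilcoxon rank-sum tests per
metric at α = 0.05 (exact for small untied samples), plus a bias report
comparing fully-automatic against semi-automatic tracking of the same
clips.

## Worked example

Simulate a 12-second clip with known ground truth, run the full
pipeline on it, and compare a synthetic expert/novice cohort:

```r
library(lapMotion)

prof <- skillProfile(stepScale = 0.12, smoothness = 0.8, jerkRate = 0.03,
                     jerkMagnitude = 0.4, durationFrames = 300L)
gt <- generateTrajectory(prof, seed = 7, start = c(3.2, 2.4),
                         bounds = c(1.8, 4.6, 1.4, 3.4),
                         config = metricsConfig(0.25))
rv <- renderVideo(gt$trajectory, cameraProfile(), seed = 7,
                  config = metricsConfig(0.25))
rv$frames
#> FrameSource: 300 frames of 320 x 240 px at 25 fps (12.0 s)

traj  <- trackPoint(rv$frames,
                    round(as.numeric(rv$truth@pixelTrajectory[1, c("x", "y")])))
calib <- trackLines(rv$frames,
                    round(as.numeric(rv$truth@lineEndpoints[1, -1])), 1, 1)
m <- computeMetrics(applyScaling(traj, perFrameScales(calib), "average"),
                    metricsConfig(0.25))
m
#> MotionMetrics (one procedure)
#>   N = 300 frames at 25 fps; T = 12.000 s
#>   D = 14.316 cm; D-bar = 0.0479 cm/frame; S-bar = 1.193 cm/s
#>   E = 5 extreme steps (d_th = 0.25 cm), 294 below; 71.6 cm/min
rv$truth@trueMetrics
#> MotionMetrics (one procedure)
#>   N = 300 frames at 25 fps; T = 12.000 s
#>   D = 14.055 cm; D-bar = 0.0470 cm/frame; S-bar = 1.171 cm/s
#>   E = 5 extreme steps (d_th = 0.25 cm), 294 below; 70.3 cm/min
```

The tracked path length (14.32 cm) recovers the ground truth
(14.05 cm) within 2 %, and the extreme-movement count exactly. A
cohort of 6 expert-like and 23 novice-like subjects separates cleanly:

```r
co <- generateCohort(nExpert = 6L, nNovice = 23L, seed = 42)
runCompare(co)[, c("metric", "median_a", "median_b", "U", "p_value")]
#>               metric median_a median_b U   p_value
#> 1     path_length_cm  36.3288 206.9859 0 0.0002261
#> 2       mean_step_cm   0.0485   0.2763 0 0.0002261
#> 3    mean_speed_cm_s   1.2110   6.8995 0 0.0002261
#> 4      extreme_count   9.0000  59.0000 0 0.0002245
#> 5 path_per_minute_cm  72.6577 413.9718 0 0.0002261
```

Here group *a* is the expert-like cohort: shorter path, smaller average
movements, fewer extreme movements, all significant at α = 0.05. (The
synthetic profiles are chosen for a detectable contrast, not to
reproduce any particular clinical cohort.)

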