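---
title: "Video motion tracking for surgical-skill metrics: methods and design"
author: "lapMotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video motion tracking for surgical-skill metrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapMotion)
```

## The problem

Objective assessment of laparoscopic skill is usually done with motion
tracking hardware: instrumented trocars, optical or electromagnetic
sensors, or simulator rigs. None of that is available for a routine
operating-room recording. lapMotion implements a software-only
alternative: a single well-chosen point on the instrument (its first
joint) is tracked through the recorded video, the pixel trajectory is
converted to centimetres using visible structures of known physical
size, and a small set of kinematic criteria — path length, average
per-frame movement, speed, and the count of extreme movements — is
computed per procedure and compared between cohorts (e.g. expert vs
novice surgeons) with rank-based statistics.

## Point tracking

`trackPoint()` is a template tracker at integer pixel resolution. The
template is the square patch of side $2r+1$ (default $r = 10$ px)
centred on the last accepted location; in the next frame every candidate
centre within the search window (default radius 25 px) is scored by
normalized cross-correlation (NCC),

$$\rho(c) \;=\; \frac{\sum_p \bigl(W_c(p)-\bar W_c\bigr)\bigl(T(p)-\bar T\bigr)}
{\sqrt{\sum_p (W_c(p)-\bar W_c)^2}\;\sqrt{\sum_p (T(p)-\bar T)^2}},$$

where $T$ is the template and $W_c$ the candidate patch. NCC is
invariant to affine intensity changes, which is what makes tracking
robust to the global illumination drift typical of endoscopic video; the
package's tests assert this invariance exactly. Patches reaching past
the frame border are zero-padded. Internally the score map is computed
with an FFT cross-correlation for the numerator and integral-image box
sums for the local means and variances; the two routes are algebraically
identical to the definition above, and scores within $10^{-9}$ of the
maximum are treated as tied (ties are resolved by smallest displacement
from the previous location, then row-major order), so floating-point
noise in the FFT cannot change a decision.

Decisions per frame:

* best score $\ge$ `confidenceFloor` (default 0.5): the location is
  accepted with status `auto` and the template is refreshed there.
  Refreshing tolerates the gradual appearance change of a moving
  instrument; `refreshTemplate = FALSE` keeps the seed template for the
  whole run.
* a frame listed in the corrections table: the supplied location is
  taken with status `manual` (the semi-automatic workflow: an operator
  checks the overlay and relocates the point where the tracker drifted
  or the instrument re-entered the view).
* best score below the floor in semi-automatic mode: status `gap`. The
  template and last accepted location are kept, so the point re-acquires
  automatically if the match recovers, or via a manual correction.
* in fully-automatic mode corrections are ignored and a lost point is
  re-acquired as the global best match over the whole frame. Low-scoring
  re-acquisitions do not refresh the template — otherwise a blank
  occlusion would overwrite the template and the tracker could never
  recover.

Matching is deliberately integer-pixel: the metrics below work on
centimetre-scaled pixel coordinates and sub-pixel refinement would add
complexity without changing any reported criterion noticeably (the
tracker's RMSE on rendered ground truth is already well under one
pixel). Coordinates use the image convention: origin top-left, x right,
y down, frames indexed 1..N.

`trackLines()` tracks the four endpoints of the two calibration lines
independently with the same machinery; a frame is valid for calibration
only when all four endpoints matched.

## Pixel-to-centimetre calibration

The camera-to-site distance varies within and between recordings, so raw
pixel displacements are not comparable. Two reference lines of known
real length $L_1, L_2$ (cm) are drawn along the instrument's second
segment, perpendicular to each other. With per-frame pixel vectors
$(\Delta x_i, \Delta y_i)$, the axis scales $s_x, s_y$ (cm/px) must give
each line its real length:

$$s_x^2\,\Delta x_i^2 + s_y^2\,\Delta y_i^2 = L_i^2, \qquad i = 1, 2,$$

a linear system in $(s_x^2, s_y^2)$ solved by `solveAxisScales()`. This
is the minimal model that captures the in-plane foreshortening caused by
the instrument's out-of-plane tilt as axis-anisotropic scale; it is why
a *pair* of perpendicular lines is used rather than one. The system is
singular when both lines constrain the same axis combination (e.g. both
parallel to one image axis) and inconsistent geometries (no positive
solution) are rejected; both raise distinct classed errors. At seeding,
lines more than 10° from perpendicular trigger a warning but proceed —
the solve only needs non-singularity, and perfect perpendicularity
cannot be clicked anyway.

`perFrameScales()` solves every valid frame; frames with a lost endpoint
inherit the nearest preceding valid scale (leading invalid frames take
the first valid one). `applyScaling()` then converts the trajectory
either with the per-axis *average* of the frame scales (the default:
one effective scale for the procedure) or *per frame*, which compensates
zooming and distance changes frame by frame. Scaling is applied about
the pixel origin; every metric below is translation-invariant, so the
choice of origin is immaterial (and tested). With per-frame scaling the
pipeline is exactly zoom-equivariant: multiplying all pixel coordinates
and line vectors by $k$ multiplies the scales by $1/k$ and leaves the cm
trajectory unchanged.

## Kinematic criteria

With scaled coordinates $(x'_n, y'_n)$, $n = 1..N$, at $f$ frames/s:

| quantity | formula | units |
|---|---|---|
| step distance | $d_{n+1} = \sqrt{(x'_{n+1}-x'_n)^2 + (y'_{n+1}-y'_n)^2}$ | cm |
| total time | $T = N/f$ | s |
| path length | $D = \sum_{n=1}^{N-1} d_{n+1}$ | cm |
| average movement | $\bar D = D/(N-1)$ | cm/frame |
| average speed | $\bar S = D/T$ | cm/s |
| extreme movements | $E = \#\{\,d_{n+1} \ge d_{th}\,\}$ | count |
| path per minute | $60\,D/T$ | cm/min |

The extreme-movement threshold $d_{th}$ defaults to 1 cm per frame; the
comparison is $\ge$ because that is the precise indicator definition,
with `strictInequality = TRUE` flipping to $>$ for users who read
"more than" literally. A larger preset of 3.5 cm, sometimes used for
"sudden" movements, is available by passing
`metricsConfig(3.5)` — neither value is privileged by the code. The
complementary below-threshold count is reported alongside, and
$E + \text{below}$ always equals the number of counted steps.

**Gaps.** When the instrument is occluded or out of view for $k$ frames
and then relocated, the default policy `interpolate_uniform` assumes the
movement between the last tracked point $A$ and the relocated point $B$
happened uniformly: $k+1$ equal steps of $|B-A|/(k+1)$. The alternative
`exclude` counts the bridge as a single step of $|B-A|$. The two
policies give the same $D$ but different step counts, hence different
$E$; both are exposed because the right imputation is genuinely
case-dependent. $\bar D$ always uses the $N-1$ denominator regardless of
gaps, keeping it comparable across procedures of equal length.
Unbridged leading or trailing gap runs contribute nothing.

## Cohort statistics

`compareGroups()` performs the two-sided Mann–Whitney/Wilcoxon rank-sum
test. A signed-rank test is sometimes named in this context, but it is a
paired test and undefined for independent groups of unequal size such as
6 experts vs 23 novices — the rank-sum test is the applicable rank test
for that design, and that is what the package implements (via
`stats::wilcox.test`): exact null distribution when the combined sample
is at most 20 without ties, normal approximation with tie and continuity
correction otherwise. The tests verify the exact path against full
enumeration of all $\binom{n_A+n_B}{n_A}$ rank assignments and the null
rejection rate against its binomial bounds. Significance is declared at
$\alpha = 0.05$, two-sided, with no multiplicity correction — a handful
of pre-specified criteria, following the original workflow.

`biasAssessment()` quantifies what manual verification buys: the same
clips are tracked semi-automatically and fully automatically and the
per-procedure relative difference $(\text{auto}-\text{semi})/\text{semi}$
is reported with its median and an outlier list (default flag at 25 %
absolute relative difference; the threshold is a reporting convention,
not a test). On occlusion-free clips the two modes agree *exactly*, so
any difference is attributable to occlusion handling — typically the
automatic re-acquisition latching onto the wrong pixel, which is exactly
the failure mode the report is designed to surface.

`summaryBoxstats()` uses the median-of-halves quartile convention (the
median is excluded from both halves for odd $n$); the convention is
fixed and documented because quartile conventions differ across software
and silently change box-plot whiskers.

## Synthetic ground truth

The generator exists so that every stage has a testable oracle.

`generateTrajectory()` draws a smoothed random walk: raw steps of
magnitude `stepScale` in uniformly random directions, exponentially
smoothed with weight `smoothness`, so ordinary steps never exceed
`stepScale`; with probability `jerkRate` a frame's step is replaced by a
jerk of magnitude exactly `jerkMagnitude`, bypassing the smoother. The
construction makes the extreme-movement count a clean binomial quantity
whenever $d_{th}$ lies strictly between `stepScale` and
`jerkMagnitude`, which the tests exploit. The expert-like default
profile (step 0.12 cm, smoothness 0.85, jerk rate 0.01) and novice-like
profile (step 0.18 cm, smoothness 0.6, jerk rate 0.08) encode the
qualitative contrast — shorter, smoother, rarer-jerk motion for experts —
at a desk-realistic 25 fps. They are deliberately *not* calibrated to
reproduce any published cohort's medians: that would make cohort-level
validation circular. They are only meant to produce a detectable
contrast.

`renderVideo()` projects the cm trajectory through a camera with
per-frame zoom and translation (`px = cm · zoom / baseScale + t`), and
draws a dark background with a two-segment instrument: a bright solid
joint marker, a trailing shaft, and the second segment carrying the two
perpendicular calibration lines, each endpoint with its own marker.
Because NCC is invariant to intensity scaling, the five tracked markers
differ in *shape* (solid, plus, cross, hollow, diamond), not merely in
brightness — early versions with identical shapes let an endpoint
tracker jump to the brighter joint marker. Frames can be occluded
(instrument omitted) and a decoy joint-lookalike can be drawn during the
occlusion to reproduce the wrong-pixel re-acquisition failure of
fully-automatic tracking. Rendering is deterministic given a seed.

What the renderer does **not** emulate: tissue appearance and motion,
specular highlights, smoke, lens distortion, interlacing, compression
artefacts, or true 3-D perspective (the camera model is an anisotropic
2-D scale plus translation). Passing tests on synthetic clips therefore
validate the *algorithms* — matching, calibration algebra, gap handling,
metric arithmetic, statistics — not robustness to clinical image
conditions, which only real video can establish.

## Numerical and validation choices

* Tracker scores are clamped to $[-1, 1]$; flat patches or a flat
  template score 0, so blank frames fall below any positive confidence
  floor.
* The 2×2 calibration solve rejects determinants below a scaled machine
  epsilon; recovery of known anisotropic scales on random perpendicular
  pairs is asserted to $10^{-9}$ over 1000 draws.
* Validation problem sizes: 300-frame clips (12 s at 25 fps) for tracker
  and end-to-end recovery, 80–120-frame clips for mode-equivalence and
  occlusion scenarios, 2000 replicates for the null rejection rate, and
  trajectory-only cohorts of 6 vs 23 subjects at 750 frames each.
  These sizes make the full validation run in minutes while keeping
  every assertion statistically meaningful; full-length procedures
  (tens of minutes) change nothing algorithmic.
* All RNG use is seeded and restores the caller's RNG state
  (`generateTrajectory`, `renderVideo`, `generateCohort`).

## Limitations

* Tracking quality depends on the seeded point being locally
  distinctive; a textureless or symmetric neighbourhood gives ambiguous
  matches that only manual corrections can fix.
* The calibration model is 2-D: residual error from genuine perspective
  (lines at very different depths) is not modelled, only the first-order
  anisotropy.
* The rank-sum test assumes independent subjects; repeated procedures by
  the same surgeon would need a different design.
* Metric values depend on the chosen window of the procedure; the
  package computes metrics for whatever frame range it is given and
  leaves window selection to the analyst.
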