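---
title: "Quantifying odor-guided honeybee search flight: methods and design"
author: "beeflight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying odor-guided honeybee search flight: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeflight)
```

## The measurement problem

A foraging honeybee trained to a feeder inside a wind tunnel is released,
and five seconds later air — with or without an attractive odor — is pushed
through a pipe 50 cm upwind of the trained position. An overhead camera
records the flight at 640 × 480 px and 30 fps for up to a minute. The
scientific questions are spatial and kinematic: where does the bee spend its
time (around the remembered feeder or around the odor source), how quickly
does it redirect after odor onset, and does its turning behavior differ
inside versus outside the region the odor actually reaches?

`beeflight` implements the full measurement chain for this design: video →
trajectory → kinematics → occupancy and plume statistics, plus a
ground-truthed synthetic generator so that every stage can be validated
without the original recordings (which were never deposited).

## Tracking

The bee is the only moving object on a white arena, so segmentation is
background subtraction: the background is the **per-pixel temporal median**
of the frames (robust to the transient bee; up to 101 evenly spaced frames
are used, which is ample for a median), and a pixel is foreground when
`|frame − background| > diffThreshold` (default 40 on the 0–255 scale).
Foreground pixels are grouped into **8-connected components**; components
smaller than `minBlobPx` (default 6 px) are noise; the centroid (unweighted
mean of pixel coordinates) of the largest surviving component is the bee's
representative point. An equal-area tie is broken toward the previous
detection, or scan order when there is none — a deterministic rule that
matters only in degenerate frames.

Pixel centers map to arena centimeters by `(k + 0.5) / pxPerCm`, with the
origin at the arena corner nearest the entrance and x increasing upwind.
This convention makes upwind speed the signed x-velocity. Detection gaps of
at most `maxGapFrames` (default 5) are bridged by linear interpolation and
flagged `valid = FALSE`; longer gaps stay missing. Interpolated samples are
excluded from occupancy maps — residence time should reflect observation,
not imputation — but they do provide positions for gap-tolerant kinematics.

Trajectories are smoothed with a centered **5-point moving average** before
analysis. At the series ends the window shrinks symmetrically (3-point at
the second sample, 1-point at the first) so the filter never extrapolates;
around missing samples it shrinks the same way so no NA enters an average.
Because the filter is linear, applying it before or after the px→cm scaling
is equivalent.

## Kinematics

With positions \((x_i, y_i)\) at spacing \(\Delta t = 1/30\) s:

* ground speed \(v_{ground,i} = \sqrt{\Delta x_i^2 + \Delta y_i^2}/\Delta t\),
* upwind speed \(v_{upwind,i} = s\,\Delta x_i/\Delta t\) with \(s = \pm 1\)
  the upwind sign (positive toward the odor source),
* movement heading \(\theta_i = \mathrm{atan2}(\Delta y_i, \Delta x_i)\),
* angular velocity \(\omega_i = \mathrm{wrap}(\theta_{i+1} - \theta_i)/\Delta t\),
  with the difference wrapped to \((-180°, 180°]\) so a heading passing
  through ±180° is a small turn, not a ±358° one.

\(|v_{upwind}| \le v_{ground}\) holds identically (a component never exceeds
the magnitude). Steps with zero displacement have undefined heading and
propagate NA — hovering must not masquerade as straight flight.
Counterclockwise is positive; comparisons use \(|\omega|\). All series have
length \(n-1\) and are indexed by step start times; \(\omega\) needs two
consecutive steps, so its last element is NA.

The direction-to-target angle is the signed difference between the movement
heading and the bearing to a target (pipe or feeder), 0° meaning straight
at it, +90° perpendicular to the left. Direction histograms bin
\((-180°, 180°]\) right-closed.

## Plume estimation and occupancy

During the airflow visualization the arena is black-papered and smoke is
bright, so smoke masks threshold `frame − background` on the bright side
(the bee, dark on white, uses the opposite polarity). The odor spread area
is the **union of all smoke masks**, regridded to 2.5-cm cells: a cell is
inside if any of its pixels was ever smoke. The 2.5-cm resolution matches
the occupancy maps for direct overlay. All spatial binning is half-open —
cell \(k\) covers \([k \cdot 2.5, (k+1) \cdot 2.5)\) — so boundary points
belong to the higher-index cell, identically in plume and occupancy code.
One special case: if the pipe sits exactly on a cell boundary, cell-center
sampling of the synthetic cone would leave the apex cell empty, so the
source's cell is always inside.

Occupancy ("remaining time rate") maps assign every valid sample to its
cell and normalize to fractions; over the default 140 × 50 cm camera view
at 2.5 cm this is the 56 × 20 grid of the original analysis. Pooling
across trajectories is the default; equal-weight per-bee averaging is
available (`pool = FALSE`) since the original report does not say which was
used. The within-radius residence (15 cm around the pipe) uses exact point
distances, not cells.

## Trials, groups and tests

Arrival at the pipe is the first time after stimulus onset within a
**3-cm capture radius** (a point pipe has no extent; the radius is
configurable). Latency groups are Under3 \([0, 3]\), Under10 \((3, 10]\),
Over10 \((10, \infty)\), NoArrival — right-closed so every latency has one
group, with 0 (already at the pipe at onset) in Under3.

Comparisons are nonparametric and two-sided throughout, with no
multiple-testing correction, matching the original analysis:

* **Mann–Whitney U** with midrank ties; exact p when \(n_a + n_b \le 12\)
  and the pooled sample is tie-free (via `stats::wilcox.test`), otherwise
  the normal approximation with tie and continuity corrections. The test
  suite checks the exact p against full enumeration of every split with
  \(n_a + n_b \le 10\).
* **Friedman test** with within-block midranks and tie-corrected
  \(\chi^2\) statistic, asymptotic p on \(k-1\) df; an exact p by
  enumerating all \((k!)^n\) within-block permutations is available for
  \(k \le 3, n \le 6\). A caveat found while validating: at \(n = 6\) the
  exact null distribution is coarsely discrete, so exact and asymptotic p
  can differ by ~0.1 in the mid-range; in the rejection tail (asymptotic
  p < 0.05) they agree within 0.01. Power/size work should use block counts
  where the asymptotic approximation is calibrated (attained size 0.050 at
  \(k = 3, n = 30\), measured at 8000 null replicates).

The inside/outside comparison takes the last 3 s before arrival, labels
each step by the plume membership of its **start** position (a straddling
step is not split), and runs Mann–Whitney U on ground speed and
\(|\omega|\), pooled across trials by default.

## The synthetic generator

`simulateFlight()` is a discrete-time correlated random walk at 30 Hz with
two behavioral regimes:

* **memory-guided** (clean air): weak attraction toward the trained feeder
  (goal-rotation capped at 3°/step) with wide turn noise
  (`turnSdOut` = 24°/step), producing the broad, tunnel-wide search seen
  without odor;
* **odor-guided**: after onset plus a per-trial switch delay, the goal
  becomes the pipe (rotation toward it at `upwindBias` = 0.3 of the bearing
  error, capped at `biasMaxDeg` = 12°/step) and the turn-noise SD depends on
  plume membership: 8°/step inside versus 24°/step outside (ratio 3). The
  state dependence encodes, as a generative assumption, the sharp turning
  observed at the plume border.

Step length is the jittered ground speed (0.4 ± 0.08 m/s per step,
floored at 0.05 m/s) times \(\Delta t\); walls reflect, with a 0.6-cm
body-radius margin (a real bee's center cannot touch a wall, and an
unclipped disc is what the renderer assumes). The per-step goal-attraction
cap is essential: without it, the attraction term dominates turning
whenever the bee circles its goal and erases the inside/outside contrast
the generator is meant to encode.

The plume is a Gaussian cone: apex at the pipe, axis downwind, core SD
1.5 cm growing with half-angle 10° out to 70 cm; the mask thresholds at
\(e^{-2}\) (the two-SD edge). `renderFrames()` draws a dark disc
(intensity 60, radius 0.6 cm) on a bright background (220) with Gaussian
pixel noise; `renderSmokeFrames()` draws stochastic bright puffs whose
per-frame visibility is proportional to concentration, so superimposing
~40 frames recovers the full spread area.

`simulateTrialSet()` draws switch delays per requested latency group
(Under3: 0–0.3 s, Under10: 3–6.5 s, Over10: 10–16 s — travel from the
feeder region adds ~1.5–3 s) and labels trials with the *pipeline's*
arrival detector, not the generator's, so group realization is itself an
end-to-end check. All randomness is seeded and local: generator functions
restore the caller's RNG state, and identical seeds give bit-identical
trajectories, frames and downstream reports.

What the generator does *not* emulate: airspeed/wind coupling (tunnel wind
is ≤ 0.1 m/s and ignored), wingbeat and body-orientation detail, moth-style
programmed zigzag/loop sequences, occlusions or lighting drift in the
video, and time-resolved plume meander (the plume is static, as in the
smoke measurement). Passing tests therefore validate the measurement chain
and the direction of the behavioral contrasts, not any biological
mechanism.

## Calibration choices worth knowing

* **Residence contrast.** With the real geometry, a feeder-centered
  clean-air search spends at most a few percent of its time within 15 cm of
  the pipe, while odor trials spend most of the post-arrival period there;
  the generator's odor:clean residence contrast is therefore much larger
  than the ~4:1 one might pick as a minimal effect. The comparison (20 vs
  20 trials, Mann–Whitney) replicates in 100/100 repetitions either way.
* **Ground-speed "no difference" is an effect-size statement.** The
  5-point smoother attenuates measured speed slightly more where turning is
  high, so pooled inside/outside samples (n ≈ 2000) yield a *statistically*
  significant but small ground-speed difference (means ~6% apart at the
  defaults). At that n a p-value detects the smoother itself; the
  meaningful matched-speed check is an equivalence bound — pooled mean
  ground speeds within 10% — which holds in 100/100 repetitions, while
  \(|\omega|\) differs by ~70% and rejects in 100/100.
* **Problem sizes.** Validation runs use 20–30 s trials, 600-frame
  renders, 100 repetitions for the directional replications, and 1000
  replicates for the type-I checks — sizes at which every rate reported is
  stable to the second decimal.

## Limitations

Single overhead camera: no altitude, so speeds are floor-projected.
Single-animal assumption: the tracker keeps the largest blob and cannot
maintain identities. The plume is treated as a static area, as in the smoke
visualization; real instantaneous filaments are narrower and intermittent.
Thresholds (`diffThreshold`, smoke threshold, capture radius) are config
parameters because the original report does not state them; defaults were
chosen on synthetic data and should be revisited for new footage.
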