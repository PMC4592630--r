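# beeflight

Video-based analysis of honeybee search flight in a wind tunnel.

A trained forager is released into a 180 × 50 × 50 cm tunnel; five seconds
later, air with or without an attractive odor flows from a pipe 50 cm
upwind of the trained feeder position, and an overhead camera records the
flight (640 × 480 px, 30 fps, ≤ 60 s). `beeflight` turns such recordings
into quantitative behavior:

* **tracking** — background-subtraction centroid detection per frame
  (temporal-median background, 8-connected blobs), gap interpolation, and
  5-point moving-average smoothing;
* **kinematics** — ground speed
  $v_{ground} = \sqrt{\Delta x^2 + \Delta y^2}/\Delta t$, signed upwind
  speed $v_{upwind} = s\,\Delta x/\Delta t$, angular velocity
  $\omega = \mathrm{wrap}(\Delta\theta)/\Delta t$ (°/s), and
  direction-to-target angles with histograms;
* **plume** — the odor spread area as the union of thresholded
  smoke-visualization frames on a 2.5-cm arena grid, with point-in-plume
  queries;
* **occupancy** — remaining-time-rate maps (56 × 20 cells at 2.5 cm over
  the camera-covered 140 × 50 cm), time-sliced maps, and within-radius
  residence fractions (15 cm around the pipe);
* **statistics** — arrival latencies and Under3/Under10/Over10 grouping,
  per-second before/after-onset summaries, Mann–Whitney U (exact or
  corrected-normal) and Friedman (tie-corrected χ², exact enumeration for
  small designs), and inside/outside-plume comparisons of speed and
  turning;
* **synthetic data** — a seeded correlated-random-walk generator with
  memory-guided and odor-guided regimes, a Gaussian-cone plume, and frame
  rendering, so the whole chain is testable without real recordings.

Everything is exposed as S4 classes (`Trajectory`, `PlumeMask`,
`OccupancyMap`, `Trial`, …) with accessors; a thin CLI lives in
`inst/scripts/beeflight`.

## Worked example

Simulate one odor-guided trial, render its video, and analyze it back from
the pixels:

```r
library(beeflight)
cal    <- ArenaCalibration()
params <- SimParams(durationS = 30, seed = 42)

sim  <- simulateFlight(params)
fs   <- renderFrames(sim$trajectory, cal, noiseSd = 5, seed = 1)
fs
#> FrameSequence: 901 frames of 229 x 640 px at 30 fps (30.03 s)

traj <- smoothTrajectory(buildTrajectory(fs, cal))
traj
#> Trajectory: 901 samples, dt = 0.03333 s (30.03 s), 901 valid detections

arr <- arrivalTime(traj, cal@pipeXY, captureRadiusCm = 3, onsetS = 5)
assignGroup(arr)
#> arrival 2.13 s after onset -> group "Under3"

remainingRateWithinRadius(traj, cal@pipeXY, 15, c(5, 30))
#> 0.82   # fraction of post-onset time within 15 cm of the pipe
```

The bee redirects to the odor source about two seconds after onset and
then spends 82% of the remaining recording within 15 cm of the pipe. A
single trial is underpowered for the turning contrast; pooling the last
3 s before arrival across 24 simulated arrivals:

```r
p      <- SimParams(durationS = 25)
mask   <- simulatePlume(p)$mask
trials <- simulateTrialSet(24, mix = c(Under3 = .5, Under10 = .5, Over10 = 0),
                           params = p, seed = 42)
arrived <- Filter(function(tr) !is.na(tr@arrivalS), trials)
samp <- do.call(rbind, lapply(arrived, insideOutsideSamples, mask = mask))
mannWhitneyU(samp$omegaAbs[samp$inside], samp$omegaAbs[!samp$inside])
#> TestResult (mann_whitney_u): statistic = 3.995e+05, p = 3.278e-35, n = 1156/1000
```

Mean $|\omega|$ is 179 °/s inside versus 304 °/s outside the plume — the
sharp turning just outside the odor border — while mean ground speeds stay
within ~6% of each other (0.388 vs 0.364 m/s).

See `vignettes/beeflight-methods.Rmd` for the models, conventions and
design decisions.

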