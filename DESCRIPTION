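Package: beeflight
Title: Wind-Tunnel Honeybee Flight Tracking and Odor-Plume Search Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Video-based analysis of honeybee search flight in a wind tunnel:
    background-subtraction centroid tracking of a single bee from grayscale
    frame sequences, trajectory smoothing and flight kinematics (ground speed,
    upwind speed, angular velocity, direction to target), smoke-visualization
    odor-plume area estimation, remaining-time-rate occupancy maps,
    latency-based trial grouping, and nonparametric inside/outside-plume
    comparisons (Mann-Whitney U, Friedman). Includes a ground-truthed
    synthetic generator (correlated random walk in two behavioral regimes,
    Gaussian-cone plume, rendered frames) so every pipeline stage is testable
    without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, tools, png, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
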