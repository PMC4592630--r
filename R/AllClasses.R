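#' @import methods
NULL

#' Frame sequence
#'
#' An ordered sequence of grayscale raster frames from an overhead camera,
#' stored as numeric matrices with intensities on the 0--255 scale
#' (rows = image rows, columns = image columns).
#'
#' @slot frames list of numeric matrices, all of identical dimensions.
#' @slot fps frames per second (30 for the wind-tunnel recordings).
#' @slot origin free-text acquisition metadata.
#' @export
setClass("FrameSequence",
  representation(frames = "list", fps = "numeric", origin = "character"),
  prototype(origin = ""))

setValidity("FrameSequence", function(object) {
  if (length(object@frames) < 1L) return("sequence non-empty: no frames")
  if (!all(vapply(object@frames, is.matrix, logical(1))))
    return("frames must be matrices")
  d <- dim(object@frames[[1L]])
  same <- vapply(object@frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) return("inconsistent frame size")
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    return("fps must be a single positive number")
  TRUE
})

#' Arena calibration
#'
#' Geometry of the camera-covered portion of the wind tunnel and the
#' pixel-to-cm scale. The coordinate convention places the origin at the
#' arena corner nearest the entrance on the camera's left; x increases
#' upwind (toward the fans and the odor pipe), y runs across the tunnel.
#' With this convention upwind speed is simply the signed x-velocity times
#' \code{upwindSign}.
#'
#' @slot pxPerCm pixels per cm.
#' @slot arenaLengthCm long-axis extent covered by the camera (cm).
#' @slot arenaWidthCm short-axis extent (cm; 50 for the tunnel).
#' @slot feederXY feeder/training position, c(x, y) in cm.
#' @slot pipeXY odor-pipe position, c(x, y) in cm (50 cm upwind of the feeder).
#' @slot upwindSign +1 or -1: sign of increasing x toward the wind source.
#' @export
setClass("ArenaCalibration",
  representation(pxPerCm = "numeric", arenaLengthCm = "numeric",
                 arenaWidthCm = "numeric", feederXY = "numeric",
                 pipeXY = "numeric", upwindSign = "numeric"))

setValidity("ArenaCalibration", function(object) {
  if (object@pxPerCm <= 0) return("pxPerCm must be > 0")
  if (object@arenaLengthCm <= 0 || object@arenaWidthCm <= 0)
    return("arena extents must be > 0")
  inArena <- function(p)
    p[1] >= 0 && p[1] <= object@arenaLengthCm &&
    p[2] >= 0 && p[2] <= object@arenaWidthCm
  if (length(object@feederXY) != 2L || !inArena(object@feederXY))
    return("feeder must lie inside the arena")
  if (length(object@pipeXY) != 2L || !inArena(object@pipeXY))
    return("pipe must lie inside the arena")
  if (!object@upwindSign %in% c(-1, 1)) return("upwindSign must be +1 or -1")
  TRUE
})

#' Bee trajectory
#'
#' A time-ordered sequence of 2-D positions in arena cm coordinates at a
#' fixed sampling period. Missing detections are NA with \code{valid = FALSE};
#' positions filled across short detection gaps by linear interpolation are
#' present but also flagged \code{valid = FALSE}.
#'
#' @slot t time stamps (s), strictly increasing with constant step dt.
#' @slot x long-axis positions (cm).
#' @slot y short-axis positions (cm).
#' @slot dt sampling period (s, 1/30 by default).
#' @slot valid logical per-sample detection flag.
#' @export
setClass("Trajectory",
  representation(t = "numeric", x = "numeric", y = "numeric",
                 dt = "numeric", valid = "logical"))

setValidity("Trajectory", function(object) {
  n <- length(object@t)
  if (n < 1L) return("trajectory non-empty")
  if (length(object@x) != n || length(object@y) != n ||
      length(object@valid) != n)
    return("t, x, y, valid must have equal length")
  if (length(object@dt) != 1L || object@dt <= 0)
    return("dt must be a single positive number")
  if (n > 1L) {
    steps <- diff(object@t)
    if (any(steps <= 0)) return("t must be strictly increasing")
    if (max(abs(steps - object@dt)) > 1e-6)
      return("t must advance by constant step dt")
  }
  TRUE
})

#' Blob-detection parameters
#'
#' @slot diffThreshold intensity difference above which a pixel is foreground
#'   (0--255 scale).
#' @slot minBlobPx minimum connected-component area in pixels.
#' @slot maxGapFrames longest run of missed detections bridged by linear
#'   interpolation.
#' @export
setClass("DetectionParams",
  representation(diffThreshold = "numeric", minBlobPx = "numeric",
                 maxGapFrames = "numeric"))

setValidity("DetectionParams", function(object) {
  if (object@diffThreshold <= 0 || object@diffThreshold >= 255)
    return("diffThreshold must be in (0, 255)")
  if (object@minBlobPx < 1) return("minBlobPx must be >= 1")
  if (object@maxGapFrames < 0) return("maxGapFrames must be >= 0")
  TRUE
})

#' Kinematics series
#'
#' Finite-difference flight indexes aligned to a trajectory of n samples.
#' All series have length n - 1 (one value per step); the angular-velocity
#' series needs two consecutive steps, so its final element is NA.
#'
#' @slot tMid time stamps of the difference intervals (s).
#' @slot vGround ground speed (m/s), >= 0.
#' @slot vUpwind upwind speed (m/s), signed, positive toward the wind source.
#' @slot omega angular velocity (deg/s), signed, counterclockwise positive.
#' @slot omegaAbs absolute angular velocity (deg/s).
#' @slot heading movement direction (deg, in (-180, 180]).
#' @export
setClass("KinematicsSeries",
  representation(tMid = "numeric", vGround = "numeric", vUpwind = "numeric",
                 omega = "numeric", omegaAbs = "numeric", heading = "numeric"))

setValidity("KinematicsSeries", function(object) {
  n <- length(object@tMid)
  lens <- c(length(object@vGround), length(object@vUpwind),
            length(object@omega), length(object@omegaAbs),
            length(object@heading))
  if (any(lens != n)) return("all series must share the tMid length")
  ok <- is.finite(object@vGround) & is.finite(object@vUpwind)
  if (any(abs(object@vUpwind[ok]) > object@vGround[ok] + 1e-9))
    return("|vUpwind| must not exceed vGround")
  TRUE
})

#' Odor-plume mask
#'
#' Binary occupancy of the odor spread area on the arena grid, obtained by
#' superimposing thresholded smoke-visualization frames (or synthetically).
#' Rows index the short axis (y), columns the long axis (x); cell (i, j)
#' covers the half-open square [ (j-1) res, j res ) x [ (i-1) res, i res ).
#'
#' @slot grid logical matrix; TRUE cells are inside the plume.
#' @slot resolutionCm cell edge length (cm).
#' @slot sourceXY odor-pipe position, c(x, y) in cm.
#' @export
setClass("PlumeMask",
  representation(grid = "matrix", resolutionCm = "numeric",
                 sourceXY = "numeric"))

setValidity("PlumeMask", function(object) {
  if (!is.logical(object@grid)) return("grid must be a logical matrix")
  if (object@resolutionCm <= 0) return("resolutionCm must be > 0")
  if (length(object@sourceXY) != 2L) return("sourceXY must be c(x, y)")
  TRUE
})

#' Remaining-time-rate map
#'
#' Fraction of trajectory samples falling in each spatial bin — the
#' occupancy measure of the study. Rows index the short axis (y), columns
#' the long axis (x); with the default 2.5 cm bins over a 140 x 50 cm view
#' the map is 20 x 56.
#'
#' @slot rates matrix of fractions, summing to 1 when nSamples > 0.
#' @slot binCm bin edge length (cm, 2.5 by default).
#' @slot nSamples total valid samples counted.
#' @export
setClass("OccupancyMap",
  representation(rates = "matrix", binCm = "numeric", nSamples = "numeric"))

setValidity("OccupancyMap", function(object) {
  if (object@binCm <= 0) return("binCm must be > 0")
  if (any(object@rates < -1e-12)) return("rates must be >= 0")
  if (object@nSamples > 0 && abs(sum(object@rates) - 1) > 1e-9)
    return("rates must sum to 1 when samples exist")
  TRUE
})

#' One recorded (or simulated) trial
#'
#' @slot trajectory the bee's Trajectory.
#' @slot stimulus "odor" or "clean".
#' @slot onsetS stimulus onset time (s after recording start; 5 by protocol).
#' @slot arrivalS latency from onset to first arrival at the pipe (s), or
#'   NA_real_ if the bee never arrived.
#' @slot group "Under3", "Under10", "Over10" or "NoArrival".
#' @export
setClass("Trial",
  representation(trajectory = "Trajectory", stimulus = "character",
                 onsetS = "numeric", arrivalS = "numeric", group = "character"))

setValidity("Trial", function(object) {
  if (!object@stimulus %in% c("odor", "clean"))
    return("stimulus must be 'odor' or 'clean'")
  if (object@onsetS < 0) return("onsetS must be >= 0")
  expected <- assignGroup(object@arrivalS)
  if (!identical(object@group, expected))
    return(sprintf("group '%s' inconsistent with arrivalS (expect '%s')",
                   object@group, expected))
  TRUE
})

#' Nonparametric test result
#'
#' @slot statistic the test statistic (U or chi-squared).
#' @slot pValue p-value in [0, 1].
#' @slot method "mann_whitney_u" or "friedman".
#' @slot n sample sizes (two group sizes for U; c(treatments, blocks) for
#'   Friedman).
#' @export
setClass("TestResult",
  representation(statistic = "numeric", pValue = "numeric",
                 method = "character", n = "numeric"))

setValidity("TestResult", function(object) {
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("p-value must lie in [0, 1]")
  if (!object@method %in% c("mann_whitney_u", "friedman"))
    return("unknown method")
  TRUE
})

#' Synthetic-trial simulation parameters
#'
#' Defaults encode the study conditions: 30 fps sampling, stimulus onset 5 s
#' after entry, recordings up to 60 s, plume as a Gaussian cone downwind of
#' the pipe, and sharper turning outside than inside the plume during
#' odor-guided flight (turnSdOut/turnSdIn = 3 by default).
#'
#' @slot arena ArenaCalibration.
#' @slot mode "memory_guided", "odor_guided" or "mixed".
#' @slot vMean mean ground speed (m/s).
#' @slot vSd per-step ground-speed jitter SD (m/s).
#' @slot turnSdIn heading-change SD inside the plume (deg/step).
#' @slot turnSdOut heading-change SD outside the plume (deg/step); also the
#'   single turn SD of memory-guided search.
#' @slot upwindBias fraction of the heading-to-goal error removed per step
#'   (0--1).
#' @slot biasMaxDeg cap on the goal-attraction rotation per step (deg); keeps
#'   the attraction from dominating turning when the bee circles its goal.
#' @slot plumeHalfangle cone half-angle (deg).
#' @slot plumeLengthCm downwind extent of the plume (cm).
#' @slot onsetS stimulus onset (s).
#' @slot durationS trial length (s, <= 60).
#' @slot switchDelayS latency from odor onset to the goal switch toward the
#'   pipe (s); varied per trial by [simulateTrialSet()] to realize the
#'   Under3/Under10/Over10 latency mix.
#' @slot seed RNG seed.
#' @export
setClass("SimParams",
  representation(arena = "ArenaCalibration", mode = "character",
                 vMean = "numeric", vSd = "numeric",
                 turnSdIn = "numeric", turnSdOut = "numeric",
                 upwindBias = "numeric", biasMaxDeg = "numeric",
                 plumeHalfangle = "numeric",
                 plumeLengthCm = "numeric", onsetS = "numeric",
                 durationS = "numeric", switchDelayS = "numeric",
                 seed = "numeric"))

setValidity("SimParams", function(object) {
  if (!object@mode %in% c("memory_guided", "odor_guided", "mixed"))
    return("mode must be memory_guided, odor_guided or mixed")
  if (object@vMean <= 0) return("speeds must be > 0")
  if (object@upwindBias < 0 || object@upwindBias > 1)
    return("upwindBias must lie in [0, 1]")
  if (object@turnSdIn < 0 || object@turnSdOut < 0)
    return("turn SDs must be >= 0")
  if (object@mode == "odor_guided" && object@turnSdOut < object@turnSdIn)
    return("odor_guided requires turnSdOut >= turnSdIn")
  if (object@durationS <= 0 || object@durationS > 60)
    return("durationS must be in (0, 60]")
  if (object@onsetS < 0 || object@onsetS >= object@durationS)
    return("onsetS must lie within the trial")
  TRUE
})
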