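#' Construct a FrameSequence
#'
#' @param frames list of numeric matrices (intensity 0--255), identical dims.
#' @param fps frames per second.
#' @param origin free-text acquisition metadata.
#' @return A [FrameSequence-class] object.
#' @export
FrameSequence <- function(frames, fps = 30, origin = "") {
  if (length(frames) == 0L) stop("no frames")
  new("FrameSequence", frames = frames, fps = as.numeric(fps),
      origin = as.character(origin))
}

#' Construct an ArenaCalibration
#'
#' The defaults describe the camera-covered 140 x 50 cm portion of the
#' 180-cm tunnel (the view starts about 30 cm from the entrance): feeder at
#' the tunnel center (x = 60 cm in view coordinates), odor pipe 50 cm upwind
#' of it, 640 horizontal pixels across 140 cm.
#'
#' @param pxPerCm pixels per cm.
#' @param arenaLengthCm,arenaWidthCm camera-covered extents (cm).
#' @param feederXY,pipeXY feeder and odor-pipe positions, c(x, y) cm.
#' @param upwindSign +1 if x increases toward the wind source.
#' @return An [ArenaCalibration-class] object.
#' @export
ArenaCalibration <- function(pxPerCm = 640 / 140,
                             arenaLengthCm = 140, arenaWidthCm = 50,
                             feederXY = c(60, 25), pipeXY = c(110, 25),
                             upwindSign = 1) {
  new("ArenaCalibration", pxPerCm = pxPerCm, arenaLengthCm = arenaLengthCm,
      arenaWidthCm = arenaWidthCm, feederXY = as.numeric(feederXY),
      pipeXY = as.numeric(pipeXY), upwindSign = upwindSign)
}

#' Construct a Trajectory
#'
#' @param t time stamps (s); if missing, built as (0:(n-1)) * dt.
#' @param x,y positions (cm).
#' @param dt sampling period (s).
#' @param valid per-sample detection flags (default: position not NA).
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(x, y, t = NULL, dt = 1 / 30, valid = NULL) {
  n <- length(x)
  if (is.null(t)) t <- (seq_len(n) - 1) * dt
  if (is.null(valid)) valid <- !is.na(x) & !is.na(y)
  new("Trajectory", t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
      dt = dt, valid = as.logical(valid))
}

#' Construct DetectionParams
#'
#' Defaults (threshold 40/255, minimum blob 6 px, gaps up to 5 frames
#' interpolated) track the synthetic fixtures cleanly and are all exposed in
#' the configuration file.
#'
#' @param diffThreshold foreground threshold on |frame - background|.
#' @param minBlobPx minimum component area (px).
#' @param maxGapFrames longest interpolatable detection gap (frames).
#' @return A [DetectionParams-class] object.
#' @export
DetectionParams <- function(diffThreshold = 40, minBlobPx = 6,
                            maxGapFrames = 5) {
  new("DetectionParams", diffThreshold = diffThreshold, minBlobPx = minBlobPx,
      maxGapFrames = maxGapFrames)
}

#' Construct a Trial
#'
#' The group label is derived from \code{arrivalS} via [assignGroup()].
#'
#' @param trajectory a [Trajectory-class].
#' @param stimulus "odor" or "clean".
#' @param onsetS stimulus onset (s).
#' @param arrivalS onset-to-arrival latency (s) or NA.
#' @return A [Trial-class] object.
#' @export
Trial <- function(trajectory, stimulus = c("odor", "clean"), onsetS = 5,
                  arrivalS = NA_real_) {
  stimulus <- match.arg(stimulus)
  new("Trial", trajectory = trajectory, stimulus = stimulus,
      onsetS = onsetS, arrivalS = as.numeric(arrivalS),
      group = assignGroup(arrivalS))
}

#' Simulation parameters with study-condition defaults
#'
#' Defaults: 0.4 m/s mean ground speed with 0.08 m/s per-step jitter,
#' turning SD 8 deg/step inside the plume versus 24 deg/step outside
#' (ratio 3), upwind/goal bias 0.3 per step, a 10-degree half-angle plume
#' reaching 70 cm downwind of the pipe, odor onset at 5 s, 60-s trials.
#'
#' @param arena an [ArenaCalibration-class].
#' @param mode behavioral regime.
#' @param vMean,vSd ground-speed mean and per-step SD (m/s).
#' @param turnSdIn,turnSdOut heading-change SDs (deg/step).
#' @param upwindBias heading-to-goal correction per step (0--1).
#' @param biasMaxDeg cap on the goal-attraction rotation per step (deg).
#' @param plumeHalfangle cone half-angle (deg).
#' @param plumeLengthCm downwind plume extent (cm).
#' @param onsetS stimulus onset (s).
#' @param durationS trial length (s, <= 60).
#' @param switchDelayS onset-to-goal-switch latency (s).
#' @param seed RNG seed.
#' @return A [SimParams-class] object.
#' @export
SimParams <- function(arena = ArenaCalibration(),
                      mode = c("odor_guided", "memory_guided", "mixed"),
                      vMean = 0.4, vSd = 0.08,
                      turnSdIn = 8, turnSdOut = 24,
                      upwindBias = 0.3, biasMaxDeg = 12, plumeHalfangle = 10,
                      plumeLengthCm = 70, onsetS = 5, durationS = 60,
                      switchDelayS = 0, seed = 1) {
  mode <- match.arg(mode)
  new("SimParams", arena = arena, mode = mode, vMean = vMean, vSd = vSd,
      turnSdIn = turnSdIn, turnSdOut = turnSdOut, upwindBias = upwindBias,
      biasMaxDeg = biasMaxDeg,
      plumeHalfangle = plumeHalfangle, plumeLengthCm = plumeLengthCm,
      onsetS = onsetS, durationS = durationS, switchDelayS = switchDelayS,
      seed = seed)
}
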