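#' Accessors for beeflight classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a beeflight S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSequence", function(object) length(object@frames))

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "FrameSequence", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))
#' @rdname accessors
#' @export
setMethod("fps", "FrameSequence", function(object) object@fps)

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "Trajectory", function(object) length(object@t))
#' @rdname accessors
#' @export
setMethod("nSamples", "OccupancyMap", function(object) object@nSamples)

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "Trajectory", function(object)
  data.frame(frame = seq_along(object@t) - 1L, t_s = object@t,
             x_cm = object@x, y_cm = object@y, valid = object@valid))

#' @rdname accessors
#' @export
setGeneric("samplingPeriod", function(object) standardGeneric("samplingPeriod"))
#' @rdname accessors
#' @export
setMethod("samplingPeriod", "Trajectory", function(object) object@dt)

#' @rdname accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))
#' @rdname accessors
#' @export
setMethod("rates", "OccupancyMap", function(object) object@rates)

#' @rdname accessors
#' @export
setGeneric("plumeGrid", function(object) standardGeneric("plumeGrid"))
#' @rdname accessors
#' @export
setMethod("plumeGrid", "PlumeMask", function(object) object@grid)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "TestResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setMethod("statistic", "TestResult", function(object) object@statistic)

#' @rdname accessors
#' @export
setGeneric("trialGroup", function(object) standardGeneric("trialGroup"))
#' @rdname accessors
#' @export
setMethod("trialGroup", "Trial", function(object) object@group)

#' @rdname accessors
#' @export
setGeneric("trajectory", function(object) standardGeneric("trajectory"))
#' @rdname accessors
#' @export
setMethod("trajectory", "Trial", function(object) object@trajectory)

#' Kinematics series as a data.frame
#'
#' @param x a [KinematicsSeries-class].
#' @param row.names,optional,... passed through for the generic signature.
#' @return data.frame with t_mid, v_ground, v_upwind, omega, omega_abs,
#'   heading columns.
#' @export
as.data.frame.KinematicsSeries <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(t_mid = x@tMid, v_ground = x@vGround, v_upwind = x@vUpwind,
             omega = x@omega, omega_abs = x@omegaAbs, heading = x@heading)
}

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("FrameSequence: %d frames of %d x %d px at %g fps (%.2f s)\n",
              length(object@frames), d[1], d[2], object@fps,
              length(object@frames) / object@fps))
})

setMethod("show", "Trajectory", function(object) {
  n <- length(object@t)
  cat(sprintf(
    "Trajectory: %d samples, dt = %.4g s (%.2f s), %d valid detections\n",
    n, object@dt, n * object@dt, sum(object@valid)))
})

setMethod("show", "PlumeMask", function(object) {
  cat(sprintf(
    "PlumeMask: %d x %d cells at %g cm, %d inside, source (%g, %g) cm\n",
    nrow(object@grid), ncol(object@grid), object@resolutionCm,
    sum(object@grid), object@sourceXY[1], object@sourceXY[2]))
})

setMethod("show", "OccupancyMap", function(object) {
  cat(sprintf(
    "OccupancyMap: %d x %d bins of %g cm, %d samples, peak rate %.3g\n",
    nrow(object@rates), ncol(object@rates), object@binCm, object@nSamples,
    if (length(object@rates)) max(object@rates) else NA_real_))
})

setMethod("show", "Trial", function(object) {
  cat(sprintf(
    "Trial: %s stimulus, onset %g s, arrival %s, group %s; ", object@stimulus,
    object@onsetS,
    if (is.na(object@arrivalS)) "none" else sprintf("%.2f s", object@arrivalS),
    object@group))
  show(object@trajectory)
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult (%s): statistic = %.4g, p = %.4g, n = %s\n",
              object@method, object@statistic, object@pValue,
              paste(object@n, collapse = "/")))
})
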