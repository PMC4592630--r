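#' Grid dimensions for the occupancy map
#'
#' Binning the camera-covered arena at \code{binCm} (2.5 cm by default)
#' gives the 56 x 20 map resolution of the study: 140 cm of tunnel length
#' and the full 50 cm width.
#'
#' @param cal an [ArenaCalibration-class].
#' @param binCm bin edge length (cm).
#' @return list with \code{nCols}, \code{nRows}, \code{binCm}.
#' @export
gridSpecFromArena <- function(cal = ArenaCalibration(), binCm = 2.5) {
  if (binCm <= 0) stop("binCm must be > 0")
  if (cal@arenaLengthCm <= 0 || cal@arenaWidthCm <= 0)
    stop("arena extents must be > 0")
  list(nCols = as.integer(round(cal@arenaLengthCm / binCm)),
       nRows = as.integer(round(cal@arenaWidthCm / binCm)),
       binCm = binCm)
}

# valid samples of one or many trajectories, optionally windowed [t0, t1)
collectSamples <- function(trajs, interval = NULL) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  xs <- ys <- id <- numeric(0)
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    sel <- tr@valid & !is.na(tr@x) & !is.na(tr@y)
    if (!is.null(interval))
      sel <- sel & tr@t >= interval[1] & tr@t < interval[2]
    xs <- c(xs, tr@x[sel]); ys <- c(ys, tr@y[sel])
    id <- c(id, rep(k, sum(sel)))
  }
  list(x = xs, y = ys, id = id)
}

#' Remaining-time-rate map
#'
#' Assigns every valid trajectory sample to its grid cell (half-open
#' binning) and normalizes counts to fractions of the total — the fraction
#' of recorded time the bee spent in each cell. Samples interpolated across
#' detection gaps (valid = FALSE) are excluded: residence should reflect
#' observation, not imputation.
#'
#' @param trajs a [Trajectory-class] or list of them.
#' @param spec grid spec from [gridSpecFromArena()].
#' @param pool if TRUE (default) samples are pooled across trajectories; if
#'   FALSE, per-trajectory maps are averaged with equal weight.
#' @return An [OccupancyMap-class].
#' @export
remainingTimeMap <- function(trajs, spec = gridSpecFromArena(), pool = TRUE) {
  s <- collectSamples(trajs)
  if (length(s$x) == 0L) stop("zero valid samples")
  i <- binIndex(s$y, spec$binCm, spec$nRows)
  j <- binIndex(s$x, spec$binCm, spec$nCols)
  ok <- i >= 1 & i <= spec$nRows & j >= 1 & j <= spec$nCols
  if (!all(ok)) stop("trajectory sample outside the arena grid")
  cellOf <- (j - 1L) * spec$nRows + i
  if (pool) {
    counts <- tabulate(cellOf, nbins = spec$nRows * spec$nCols)
    ratesM <- matrix(counts / length(cellOf), spec$nRows, spec$nCols)
  } else {
    ratesM <- matrix(0, spec$nRows, spec$nCols)
    ids <- unique(s$id)
    for (k in ids) {
      ck <- tabulate(cellOf[s$id == k], nbins = spec$nRows * spec$nCols)
      ratesM <- ratesM + matrix(ck / sum(ck), spec$nRows, spec$nCols)
    }
    ratesM <- ratesM / length(ids)
  }
  new("OccupancyMap", rates = ratesM, binCm = spec$binCm,
      nSamples = length(cellOf))
}

#' Remaining-time rate within a disc
#'
#' Fraction of valid samples in the time window [t0, t1) whose Euclidean
#' distance to \code{center} is at most \code{radiusCm}. The study's
#' headline occupancy comparison uses a 15 cm radius around the odor pipe.
#' Trajectory points are used directly (not grid cells) for exactness.
#'
#' @param traj a [Trajectory-class].
#' @param center c(x, y) in cm.
#' @param radiusCm disc radius (> 0).
#' @param window c(t0, t1) in s; defaults to the full trajectory span.
#' @return fraction in [0, 1].
#' @export
remainingRateWithinRadius <- function(traj, center, radiusCm = 15,
                                      window = NULL) {
  if (radiusCm <= 0) stop("radiusCm must be > 0")
  if (is.null(window))
    window <- c(traj@t[1], traj@t[length(traj@t)] + traj@dt)
  s <- collectSamples(traj, interval = window)
  if (length(s$x) == 0L) stop("empty window")
  d <- sqrt((s$x - center[1])^2 + (s$y - center[2])^2)
  mean(d <= radiusCm)
}

#' Occupancy map restricted to a time slice
#'
#' As [remainingTimeMap()] but counting only samples with t in the
#' half-open interval [t0, t1) — e.g. the first versus the next 5 s of the
#' slow-arrival trials.
#'
#' @param trajs a [Trajectory-class] or list of them.
#' @param spec grid spec from [gridSpecFromArena()].
#' @param interval c(t0, t1) in s.
#' @param pool pool samples across trajectories (default) or average
#'   per-trajectory maps.
#' @return An [OccupancyMap-class].
#' @export
timeSliceMap <- function(trajs, spec = gridSpecFromArena(), interval,
                         pool = TRUE) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  sliced <- lapply(trajs, function(tr) {
    sel <- tr@t >= interval[1] & tr@t < interval[2]
    if (!any(sel)) return(NULL)
    Trajectory(x = tr@x[sel], y = tr@y[sel], t = tr@t[sel], dt = tr@dt,
               valid = tr@valid[sel])
  })
  sliced <- Filter(Negate(is.null), sliced)
  if (length(sliced) == 0L) stop("empty time slice")
  remainingTimeMap(sliced, spec, pool = pool)
}

#' Plot an occupancy map or plume mask as a heatmap
#'
#' @param x an [OccupancyMap-class] or [PlumeMask-class].
#' @param ... passed to [graphics::image()].
#' @export
plotMap <- function(x, ...) {
  m <- if (is(x, "OccupancyMap")) x@rates else x@grid * 1
  bin <- if (is(x, "OccupancyMap")) x@binCm else x@resolutionCm
  graphics::image(x = (seq_len(ncol(m)) - 0.5) * bin,
                  y = (seq_len(nrow(m)) - 0.5) * bin,
                  z = t(m), xlab = "x (cm, upwind →)", ylab = "y (cm)",
                  useRaster = TRUE, asp = 1, ...)
}
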