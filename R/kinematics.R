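# wrap angles (degrees) to (-180, 180]
wrapDeg <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Ground speed of a trajectory
#'
#' Finite-difference speed over the tunnel floor,
#' \eqn{v_{ground}[i] = \sqrt{\Delta x_i^2 + \Delta y_i^2} / \Delta t},
#' converted cm to m. One value per step; steps touching a missing
#' position are NA.
#'
#' @param traj a [Trajectory-class] (normally smoothed first, as in the
#'   analysis pipeline).
#' @return numeric vector of length n - 1, in m/s.
#' @export
groundSpeed <- function(traj) {
  n <- length(traj@t)
  if (n < 2L) stop("need at least 2 samples")
  sqrt(diff(traj@x)^2 + diff(traj@y)^2) / traj@dt / 100
}

#' Upwind speed of a trajectory
#'
#' Signed velocity component along the tunnel long axis,
#' \eqn{v_{upwind}[i] = s \cdot \Delta x_i / \Delta t} with s the upwind
#' sign, positive toward the wind source / odor pipe; cm converted to m.
#'
#' @param traj a [Trajectory-class].
#' @param cal an [ArenaCalibration-class] supplying the upwind sign.
#' @return numeric vector of length n - 1, in m/s.
#' @export
upwindSpeed <- function(traj, cal = ArenaCalibration()) {
  n <- length(traj@t)
  if (n < 2L) stop("need at least 2 samples")
  cal@upwindSign * diff(traj@x) / traj@dt / 100
}

#' Movement heading per step
#'
#' \eqn{atan2(\Delta y, \Delta x)} in degrees, in (-180, 180]. Steps with
#' zero displacement have undefined heading and yield NA — a hovering bee
#' must not be fabricated into straight flight.
#'
#' @param traj a [Trajectory-class].
#' @return numeric vector of length n - 1, degrees.
#' @export
headingSeries <- function(traj) {
  dx <- diff(traj@x)
  dy <- diff(traj@y)
  h <- atan2(dy, dx) * 180 / pi
  h[!is.na(dx) & !is.na(dy) & dx == 0 & dy == 0] <- NA_real_
  wrapDeg(h)
}

#' Angular velocity of a trajectory
#'
#' Rate of change of the movement heading,
#' \eqn{\omega[i] = wrap(\theta_{i+1} - \theta_i) / \Delta t} in degrees/s,
#' with the heading difference wrapped to (-180, 180] (so 179 deg followed
#' by -179 deg is a +2 deg turn, not -358). Counterclockwise positive in
#' arena coordinates. The returned vector is aligned to the step series:
#' length n - 1, with the final element NA.
#'
#' @param traj a [Trajectory-class].
#' @return numeric vector of length n - 1, in deg/s.
#' @export
angularVelocity <- function(traj) {
  n <- length(traj@t)
  if (n < 3L) stop("need at least 3 samples")
  h <- headingSeries(traj)
  c(wrapDeg(diff(h)) / traj@dt, NA_real_)
}

#' All kinematic series of a trajectory
#'
#' @param traj a [Trajectory-class] (normally smoothed first).
#' @param cal an [ArenaCalibration-class].
#' @return A [KinematicsSeries-class]; all series have length n - 1 and are
#'   indexed by the step start times \code{tMid}.
#' @export
kinematics <- function(traj, cal = ArenaCalibration()) {
  n <- length(traj@t)
  if (n < 3L) stop("need at least 3 samples")
  om <- angularVelocity(traj)
  new("KinematicsSeries",
      tMid = traj@t[-n] + traj@dt / 2,
      vGround = groundSpeed(traj),
      vUpwind = upwindSpeed(traj, cal),
      omega = om, omegaAbs = abs(om),
      heading = headingSeries(traj))
}

#' Flight direction relative to a target
#'
#' Per-step signed angle between the movement vector and the bearing from
#' the current position to the target, wrapped to (-180, 180]. 0 deg means
#' flying straight at the target; +90 deg means moving perpendicular, to
#' the left of the bearing (counterclockwise). Steps starting at the target
#' itself, or with zero displacement, are NA.
#'
#' @param traj a [Trajectory-class].
#' @param target c(x, y) in cm (e.g. the odor-pipe position).
#' @return numeric vector of length n - 1, degrees.
#' @export
directionToTarget <- function(traj, target) {
  n <- length(traj@t)
  if (n < 2L) stop("need at least 2 samples")
  h <- headingSeries(traj)
  bx <- target[1] - traj@x[-n]
  by <- target[2] - traj@y[-n]
  bearing <- atan2(by, bx) * 180 / pi
  bearing[!is.na(bx) & !is.na(by) & bx == 0 & by == 0] <- NA_real_
  wrapDeg(h - bearing)
}

#' Histogram of direction angles
#'
#' Equal-width bins covering (-180, 180], right-closed, so -170 and +170
#' fall in the extreme bins and 180 in the last. Missing values are
#' excluded; fractions sum to 1 whenever any sample exists.
#'
#' @param angles numeric vector of angles in degrees (NA allowed).
#' @param nBins number of bins (>= 2).
#' @return list with \code{edges} (length nBins + 1), \code{counts} and
#'   \code{fractions} (length nBins).
#' @export
directionHistogram <- function(angles, nBins = 12) {
  if (nBins < 2) stop("nBins must be >= 2")
  a <- wrapDeg(angles[!is.na(angles)])
  width <- 360 / nBins
  edges <- seq(-180, 180, by = width)
  idx <- ceiling((a + 180) / width)
  idx[idx < 1L] <- 1L
  idx[idx > nBins] <- nBins
  counts <- tabulate(idx, nbins = nBins)
  fractions <- if (length(a)) counts / length(a) else rep(NA_real_, nBins)
  list(edges = edges, counts = counts, fractions = fractions)
}
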