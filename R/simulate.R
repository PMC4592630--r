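# run expr under a local RNG stream: seed it, restore the caller's state after
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Odor-plume concentration field (Gaussian cone)
#'
#' Relative concentration of the synthetic plume at arena positions: a
#' Gaussian cross-section whose width grows linearly with downwind distance
#' from the pipe, apex value 1 on the axis, zero upwind of the pipe and
#' beyond \code{plumeLengthCm}. The cone half-angle sets the edge at two
#' cross-section SDs, so the default mask threshold exp(-2) recovers the
#' geometric cone.
#'
#' @param params a [SimParams-class].
#' @param x,y positions (cm), vectorized.
#' @return numeric vector of relative concentrations in [0, 1].
#' @export
plumeConcentration <- function(params, x, y) {
  cal <- params@arena
  sigma0 <- 1.5                                   # core width at the pipe, cm
  d <- cal@upwindSign * (cal@pipeXY[1] - x)       # downwind distance
  w <- y - cal@pipeXY[2]
  sigma <- sigma0 + d * tan(params@plumeHalfangle * pi / 180) / 2
  conc <- exp(-w^2 / (2 * sigma^2))
  conc[d < 0 | d > params@plumeLengthCm] <- 0
  conc
}

#' Simulate the odor plume
#'
#' Evaluates the cone concentration at grid-cell centers and thresholds at
#' a fixed fraction of the apex value (exp(-2), i.e. the two-SD cone edge)
#' to produce the plume mask.
#'
#' @param params a [SimParams-class].
#' @param resolutionCm grid resolution (2.5 cm, matching the occupancy map).
#' @param maskFraction mask threshold as a fraction of the apex value.
#' @return list with \code{mask} ([PlumeMask-class]) and \code{field}
#'   (matrix of concentrations, rows = y bins).
#' @export
simulatePlume <- function(params, resolutionCm = 2.5,
                          maskFraction = exp(-2)) {
  cal <- params@arena
  if (cal@pipeXY[1] < 0 || cal@pipeXY[1] > cal@arenaLengthCm ||
      cal@pipeXY[2] < 0 || cal@pipeXY[2] > cal@arenaWidthCm)
    stop("pipe outside arena")
  spec <- gridSpecFromArena(cal, resolutionCm)
  xc <- (seq_len(spec$nCols) - 0.5) * resolutionCm
  yc <- (seq_len(spec$nRows) - 0.5) * resolutionCm
  field <- outer(yc, xc, function(yy, xx) plumeConcentration(params, xx, yy))
  grid <- field >= maskFraction
  # the apex (concentration 1) sits at the pipe itself; cell-center sampling
  # can miss it when the pipe lies on a cell boundary, so its cell is always
  # inside
  grid[binIndex(cal@pipeXY[2], resolutionCm, spec$nRows),
       binIndex(cal@pipeXY[1], resolutionCm, spec$nCols)] <- TRUE
  mask <- new("PlumeMask", grid = grid,
              resolutionCm = resolutionCm, sourceXY = cal@pipeXY)
  list(mask = mask, field = field)
}

#' Simulate one search flight
#'
#' Discrete-time correlated random walk at 30 Hz. Each step the heading is
#' rotated toward the current goal by \code{upwindBias} times the bearing
#' error, then perturbed by Gaussian turn noise; step length is the jittered
#' ground speed times dt; walls reflect. Before the stimulus onset (plus
#' \code{switchDelayS}) the goal is the trained feeder with the wide
#' (outside) turn SD — memory-guided search. After the switch, an
#' odor-guided bee heads for the pipe with turn SD \code{turnSdIn} inside
#' the plume mask and \code{turnSdOut} outside, encoding the sharper turning
#' observed at the plume border; a memory-guided bee (clean-air control)
#' keeps the feeder goal throughout.
#'
#' @param params a [SimParams-class] with mode "odor_guided" or
#'   "memory_guided".
#' @return list with \code{trajectory} ([Trajectory-class]) and
#'   \code{truth}: true positions, per-step state labels
#'   ("memory"/"odor"), true plume membership, and the true onset-to-
#'   arrival latency at 3 cm capture radius (NA if none).
#' @export
simulateFlight <- function(params) {
  if (params@mode == "mixed")
    stop("simulateFlight needs a concrete mode; use simulateTrialSet")
  cal <- params@arena
  dt <- 1 / 30
  n <- round(params@durationS / dt)
  plume <- simulatePlume(params)
  grid <- plume$mask@grid
  res <- plume$mask@resolutionCm
  nR <- nrow(grid); nC <- ncol(grid)
  noise <- withSeed(params@seed, list(
    z = stats::rnorm(n),
    v = stats::rnorm(n, params@vMean * 100, params@vSd * 100)))
  zTurn <- noise$z
  stepLen <- pmax(5, noise$v) * dt                           # cm per step
  x <- y <- member <- numeric(n + 1)
  state <- character(n + 1)
  x[1] <- 5; y[1] <- cal@arenaWidthCm / 2
  heading <- if (cal@upwindSign > 0) 0 else 180   # enter flying upwind
  switchT <- params@onsetS + params@switchDelayS
  lenCm <- cal@arenaLengthCm; widCm <- cal@arenaWidthCm
  fx <- cal@feederXY[1]; fy <- cal@feederXY[2]
  px <- cal@pipeXY[1]; py <- cal@pipeXY[2]
  deg <- 180 / pi
  for (i in seq_len(n + 1)) {
    ci <- min(nR, max(1L, floor(y[i] / res) + 1L))
    cj <- min(nC, max(1L, floor(x[i] / res) + 1L))
    member[i] <- grid[ci, cj]
    tNow <- (i - 1) * dt
    odorActive <- params@mode == "odor_guided" && tNow >= switchT
    state[i] <- if (odorActive) "odor" else "memory"
    if (i > n) break
    if (odorActive) {
      gx <- px; gy <- py
      sd <- if (member[i] > 0) params@turnSdIn else params@turnSdOut
      cap <- params@biasMaxDeg
    } else {
      # memory-guided search: weak attraction to the trained feeder gives
      # the broad, tunnel-wide search seen without odor
      gx <- fx; gy <- fy
      sd <- params@turnSdOut
      cap <- min(params@biasMaxDeg, 3)
    }
    bearing <- atan2(gy - y[i], gx - x[i]) * deg
    err <- ((bearing - heading + 180) %% 360) - 180
    rot <- params@upwindBias * err
    if (rot > cap) rot <- cap
    if (rot < -cap) rot <- -cap
    heading <- heading + rot + sd * zTurn[i]
    nx <- x[i] + stepLen[i] * cos(heading / deg)
    ny <- y[i] + stepLen[i] * sin(heading / deg)
    # reflective walls, with a bee-body margin: the body center cannot
    # reach the wall itself
    m <- 0.6
    if (nx < m) { nx <- 2 * m - nx; heading <- 180 - heading }
    if (nx > lenCm - m) { nx <- 2 * (lenCm - m) - nx; heading <- 180 - heading }
    if (ny < m) { ny <- 2 * m - ny; heading <- -heading }
    if (ny > widCm - m) { ny <- 2 * (widCm - m) - ny; heading <- -heading }
    x[i + 1] <- nx; y[i + 1] <- ny
  }
  traj <- Trajectory(x = x, y = y, dt = dt)
  tAx <- traj@t
  hit <- which(tAx >= params@onsetS &
                 sqrt((x - px)^2 + (y - py)^2) <= 3)
  arrival <- if (length(hit)) tAx[hit[1]] - params@onsetS else NA_real_
  list(trajectory = traj,
       truth = list(x = x, y = y, state = state,
                    plumeMembership = as.logical(member),
                    arrivalSTrue = arrival))
}

#' Render camera frames for a trajectory
#'
#' Bright uniform background (intensity 220) with additive Gaussian pixel
#' noise (clamped to 0--255) and a dark disc (intensity 60, radius about a
#' bee body) centered at each position converted cm to px. Samples with
#' missing positions render background only. Reproducible for a fixed seed.
#'
#' @param traj a [Trajectory-class]; positions must lie inside the arena.
#' @param cal an [ArenaCalibration-class].
#' @param noiseSd Gaussian pixel-noise SD (intensity units).
#' @param seed RNG seed.
#' @param beeRadiusCm disc radius (cm).
#' @param bgIntensity,beeIntensity background and disc intensities.
#' @return A [FrameSequence-class] at 1/dt fps.
#' @export
renderFrames <- function(traj, cal = ArenaCalibration(), noiseSd = 3,
                         seed = 1, beeRadiusCm = 0.6, bgIntensity = 220,
                         beeIntensity = 60) {
  ok <- !is.na(traj@x)
  if (any(traj@x[ok] < 0 | traj@x[ok] > cal@arenaLengthCm |
          traj@y[ok] < 0 | traj@y[ok] > cal@arenaWidthCm))
    stop("trajectory point outside arena")
  nr <- round(cal@arenaWidthCm * cal@pxPerCm)
  nc <- round(cal@arenaLengthCm * cal@pxPerCm)
  rpx <- beeRadiusCm * cal@pxPerCm
  n <- length(traj@t)
  out <- vector("list", n)
  withSeed(seed, for (i in seq_len(n)) {
    f <- matrix(bgIntensity, nr, nc)
    if (!is.na(traj@x[i])) {
      cc <- cmToPx(traj@x[i], cal)        # 0-based column center
      cr <- cmToPx(traj@y[i], cal)        # 0-based row center
      rows <- max(1L, floor(cr - rpx) + 1L):min(nr, ceiling(cr + rpx) + 1L)
      cols <- max(1L, floor(cc - rpx) + 1L):min(nc, ceiling(cc + rpx) + 1L)
      dr <- (rows - 1) - cr
      dc <- (cols - 1) - cc
      disc <- outer(dr^2, dc^2, "+") <= rpx^2
      f[rows, cols][disc] <- beeIntensity
    }
    if (noiseSd > 0) f <- f + stats::rnorm(nr * nc, 0, noiseSd)
    out[[i]] <- pmin(pmax(f, 0), 255)
  })
  FrameSequence(out, fps = 1 / traj@dt, origin = "synthetic render")
}

#' Render smoke-visualization frames for the synthetic plume
#'
#' Dark background (the walls were black-papered for the airflow
#' visualization) with bright smoke pixels. Each frame shows a stochastic
#' puff pattern: a pixel lights up when the local concentration times a
#' uniform per-pixel draw exceeds a visibility constant, so dense regions
#' appear in most frames and thin edges only occasionally — superimposing
#' frames recovers the full spread area.
#'
#' @param params a [SimParams-class].
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @param visibility puff visibility constant; lower = more visible.
#' @param noiseSd background pixel-noise SD.
#' @return A [FrameSequence-class].
#' @export
renderSmokeFrames <- function(params, nFrames = 40, seed = 1,
                              visibility = 0.12, noiseSd = 2) {
  cal <- params@arena
  nr <- round(cal@arenaWidthCm * cal@pxPerCm)
  nc <- round(cal@arenaLengthCm * cal@pxPerCm)
  xs <- pxToCm(matrix(rep(0:(nc - 1), each = nr), nr, nc), cal)
  ys <- pxToCm(matrix(rep(0:(nr - 1), nc), nr, nc), cal)
  field <- matrix(plumeConcentration(params, as.vector(xs), as.vector(ys)),
                  nr, nc)
  out <- vector("list", nFrames)
  withSeed(seed, for (i in seq_len(nFrames)) {
    f <- matrix(20, nr, nc)
    vis <- field * stats::runif(nr * nc) > visibility
    f[vis] <- 200
    if (noiseSd > 0) f <- f + stats::rnorm(nr * nc, 0, noiseSd)
    out[[i]] <- pmin(pmax(f, 0), 255)
  })
  FrameSequence(out, fps = 30, origin = "synthetic smoke render")
}

#' Simulate a set of trials with a target latency-group mix
#'
#' Draws each odor trial's onset-to-switch delay from a group-specific
#' range (Under3: 0--0.3 s; Under10: 3--6.5 s; Over10: 10--16 s) so the
#' realized arrival-latency groups approximate the requested mix; clean-air
#' control trials run memory-guided. Arrival latencies and group labels are
#' computed by the analysis pipeline ([arrivalTime()], [assignGroup()]),
#' not copied from the generator.
#'
#' @param n number of odor trials.
#' @param mix named proportions over Under3/Under10/Over10, summing to 1.
#' @param params a [SimParams-class] template.
#' @param seed RNG seed for the set.
#' @param nClean number of clean-air control trials to append.
#' @param captureRadiusCm arrival capture radius (cm).
#' @return list of [Trial-class] objects.
#' @export
simulateTrialSet <- function(n, mix = c(Under3 = 1 / 3, Under10 = 1 / 3,
                                        Over10 = 1 / 3),
                             params = SimParams(), seed = params@seed,
                             nClean = 0, captureRadiusCm = 3) {
  if (n < 0 || nClean < 0) stop("trial counts must be >= 0")
  if (n > 0) {
    if (is.null(names(mix)) ||
        !all(names(mix) %in% c("Under3", "Under10", "Over10")) ||
        any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
      stop("invalid mix: need named non-negative proportions summing to 1")
  }
  total <- n + nClean
  if (total == 0L) return(list())
  delayRange <- list(Under3 = c(0, 0.3), Under10 = c(3, 6.5),
                     Over10 = c(10, 16))
  draw <- withSeed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, total)
    groups <- if (n > 0)
      sample(names(mix), n, replace = TRUE, prob = mix) else character(0)
    delays <- vapply(groups, function(g)
      stats::runif(1, delayRange[[g]][1], delayRange[[g]][2]), numeric(1))
    list(seeds = seeds, groups = groups, delays = delays)
  })
  seeds <- draw$seeds
  delays <- draw$delays
  trials <- vector("list", total)
  for (i in seq_len(total)) {
    odor <- i <= n
    p <- params
    p@mode <- if (odor) "odor_guided" else "memory_guided"
    p@switchDelayS <- if (odor) delays[i] else 0
    p@seed <- seeds[i]
    sim <- simulateFlight(p)
    arrival <- arrivalTime(sim$trajectory, p@arena@pipeXY,
                           captureRadiusCm = captureRadiusCm,
                           onsetS = p@onsetS)
    trials[[i]] <- Trial(sim$trajectory,
                         stimulus = if (odor) "odor" else "clean",
                         onsetS = p@onsetS, arrivalS = arrival)
  }
  trials
}
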