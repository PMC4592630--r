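test_that("flight simulation is deterministic and respects degenerate params", {
  p <- SimParams(durationS = 10, seed = 51)
  a <- simulateFlight(p)
  b <- simulateFlight(p)
  expect_identical(a$trajectory@x, b$trajectory@x)
  expect_identical(a$trajectory@y, b$trajectory@y)
  expect_identical(a$truth$plumeMembership, b$truth$plumeMembership)
  # different seed, different path
  c2 <- simulateFlight(SimParams(durationS = 10, seed = 52))
  expect_false(identical(a$trajectory@x, c2$trajectory@x))

  # zero bias and zero turn noise: straight flight until a wall
  ps <- SimParams(mode = "memory_guided", upwindBias = 0, turnSdIn = 0,
                  turnSdOut = 0, vSd = 0, durationS = 10, seed = 53)
  s <- simulateFlight(ps)
  dx <- diff(s$trajectory@x)
  # before the first reflection every step is identical and forward
  firstTurn <- which(abs(diff(dx)) > 1e-9)[1]
  expect_gt(firstTurn, 10)
  expect_equal(stats::sd(dx[seq_len(firstTurn)]), 0, tolerance = 1e-12)
  expect_equal(diff(s$trajectory@y)[seq_len(firstTurn)],
               rep(0, firstTurn), tolerance = 1e-9)
})

test_that("simulated positions stay inside the arena", {
  for (seed in 54:57) {
    s <- simulateFlight(SimParams(durationS = 20, seed = seed))
    expect_true(all(s$trajectory@x >= 0 & s$trajectory@x <= 140))
    expect_true(all(s$trajectory@y >= 0 & s$trajectory@y <= 50))
  }
})

test_that("plume cone has the stated geometry", {
  p <- SimParams()
  pl <- simulatePlume(p)
  g <- plumeGrid(pl$mask)
  # apex cell contains the source
  src <- p@arena@pipeXY
  expect_true(pointInPlume(pl$mask, src))
  # strictly upwind of the pipe: never inside
  expect_false(pointInPlume(pl$mask, c(src[1] + 5, src[2])))
  expect_false(pointInPlume(pl$mask, c(139, 25)))
  # cross-section width grows monotonically downwind within the plume length
  widths <- sapply(seq_len(ncol(g)), function(j) sum(g[, j]))
  cols <- which(widths > 0)
  dists <- src[1] - (cols - 0.5) * 2.5      # downwind distance of column
  ord <- order(dists)
  expect_true(all(diff(widths[cols][ord]) >= 0))
  # beyond the plume length: empty
  beyond <- (cols - 0.5) * 2.5 < src[1] - p@plumeLengthCm
  expect_false(any(widths[cols][beyond] > 0))
})

test_that("generator self-consistency: more turning outside the plume", {
  # ground-truth labels, odor-guided defaults pooled over trials
  inAll <- outAll <- numeric(0)
  for (seed in 61:80) {
    s <- simulateFlight(SimParams(durationS = 12, seed = seed))
    k <- kinematics(s$trajectory)
    mem <- s$truth$plumeMembership[-length(s$truth$plumeMembership)]
    odor <- s$truth$state[-length(s$truth$state)] == "odor"
    inAll <- c(inAll, k@omegaAbs[odor & mem])
    outAll <- c(outAll, k@omegaAbs[odor & !mem])
  }
  expect_gt(mean(outAll, na.rm = TRUE), mean(inAll, na.rm = TRUE))
})

test_that("frame rendering is deterministic and validates positions", {
  tr <- linearTraj(n = 4, x0 = 50, dx = 1)
  f1 <- renderFrames(tr, noiseSd = 4, seed = 71)
  f2 <- renderFrames(tr, noiseSd = 4, seed = 71)
  expect_identical(frames(f1), frames(f2))
  f3 <- renderFrames(tr, noiseSd = 4, seed = 72)
  expect_false(identical(frames(f1)[[1]], frames(f3)[[1]]))
  bad <- Trajectory(x = c(50, 150), y = c(25, 25))
  expect_error(renderFrames(bad), "outside arena")
})

test_that("trial sets realize the requested latency mix", {
  # strong goal bias: quick switchers should almost all arrive within 3 s
  pStrong <- SimParams(durationS = 25, upwindBias = 0.6, biasMaxDeg = 20)
  trials <- simulateTrialSet(20, mix = c(Under3 = 1, Under10 = 0, Over10 = 0),
                             params = pStrong, seed = 81)
  groups <- vapply(trials, trialGroup, character(1))
  expect_gte(mean(groups == "Under3"), 0.8)
  p <- SimParams(durationS = 25)

  expect_identical(simulateTrialSet(0, params = p, nClean = 0), list())
  expect_error(simulateTrialSet(5, mix = c(Under3 = 0.7, Under10 = 0.7),
                                params = p),
               "invalid mix")
  # determinism of the whole set
  t1 <- simulateTrialSet(3, params = p, seed = 82)
  t2 <- simulateTrialSet(3, params = p, seed = 82)
  expect_identical(lapply(t1, function(tr) tr@trajectory@x),
                   lapply(t2, function(tr) tr@trajectory@x))
})

test_that("clean-air controls stay away from the pipe relative to odor", {
  p <- SimParams(durationS = 20)
  ts <- simulateTrialSet(8, mix = c(Under3 = 0.5, Under10 = 0.5, Over10 = 0),
                         params = p, seed = 83, nClean = 8)
  rate <- function(tr) remainingRateWithinRadius(
    trajectory(tr), p@arena@pipeXY, 15, c(p@onsetS, p@durationS))
  odor <- vapply(ts[1:8], rate, numeric(1))
  clean <- vapply(ts[9:16], rate, numeric(1))
  expect_gt(mean(odor), mean(clean))
  expect_lt(pValue(mannWhitneyU(odor, clean)), 0.05)
})

test_that("full pipeline reproduces generator ground truth end to end", {
  cal <- testArena()
  p <- SimParams(durationS = 6, seed = 91, switchDelayS = 0)
  sim <- simulateFlight(p)
  fs <- renderFrames(sim$trajectory, cal, noiseSd = 4, seed = 92)
  traj <- buildTrajectory(fs, cal)
  err <- sqrt((traj@x - sim$truth$x)^2 + (traj@y - sim$truth$y)^2) *
    cal@pxPerCm
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 1)
  # arrival latency recovered from tracked frames matches the truth
  arrTracked <- arrivalTime(traj, cal@pipeXY, 3, p@onsetS)
  expect_equal(arrTracked, sim$truth$arrivalSTrue, tolerance = 0.1)
  expect_identical(assignGroup(arrTracked),
                   assignGroup(sim$truth$arrivalSTrue))
})
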