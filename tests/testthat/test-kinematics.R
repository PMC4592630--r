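test_that("ground and upwind speed match closed forms", {
  cal <- testArena()
  # 1 cm per frame upwind at 30 fps = 0.30 m/s
  tr <- linearTraj(n = 10, dx = 1, dy = 0)
  expect_equal(groundSpeed(tr), rep(0.30, 9))
  expect_equal(upwindSpeed(tr, cal), rep(0.30, 9))

  # toward the entrance: upwind speed flips sign
  trBack <- linearTraj(n = 10, x0 = 60, dx = -1)
  expect_equal(upwindSpeed(trBack, cal), rep(-0.30, 9))
  expect_equal(groundSpeed(trBack), rep(0.30, 9))

  # pure crosswind 2 cm/frame: ground 0.60, upwind 0
  trCross <- linearTraj(n = 10, dx = 0, dy = 2, y0 = 10)
  expect_equal(groundSpeed(trCross), rep(0.60, 9))
  expect_equal(upwindSpeed(trCross, cal), rep(0, 9))

  # stationary: zero everywhere
  expect_equal(groundSpeed(linearTraj(n = 5, dx = 0, dy = 0)), rep(0, 4))

  expect_error(groundSpeed(Trajectory(x = 1, y = 1)), "at least 2")
})

test_that("angular velocity matches closed forms and wraps correctly", {
  # straight line: omega = 0
  om <- angularVelocity(linearTraj(n = 10, dx = 1, dy = 0.5))
  expect_equal(om[1:8], rep(0, 8))
  expect_true(is.na(om[9]))

  # regular polygon turning 12 deg/frame at 30 fps: omega = 360 deg/s
  nSteps <- 30
  head <- cumsum(rep(12, nSteps))
  x <- c(50, 50 + cumsum(cos(head * pi / 180)))
  y <- c(25, 25 + cumsum(sin(head * pi / 180)))
  omP <- angularVelocity(Trajectory(x = x, y = y))
  expect_equal(omP[seq_len(nSteps - 1)], rep(12 * 30, nSteps - 1),
               tolerance = 1e-9)

  # heading 179 then -179 is a +2 deg turn, not -358:
  # oracle = minimal-|delta| candidate among delta + 360k
  h1 <- 179; h2 <- -179
  cands <- (h2 - h1) + 360 * (-1:1)
  expect_equal(cands[which.min(abs(cands))], 2)
  x3 <- c(0, cos(h1 * pi / 180), cos(h1 * pi / 180) + cos(h2 * pi / 180))
  y3 <- c(0, sin(h1 * pi / 180), sin(h1 * pi / 180) + sin(h2 * pi / 180))
  om3 <- angularVelocity(Trajectory(x = x3 + 50, y = y3 + 25))
  expect_equal(om3[1], 2 * 30, tolerance = 1e-9)

  expect_error(angularVelocity(Trajectory(x = c(1, 2), y = c(1, 2))),
               "at least 3")
})

test_that("hovering yields missing heading, never fabricated zero", {
  tr <- Trajectory(x = c(10, 10, 11), y = c(5, 5, 5))
  h <- headingSeries(tr)
  expect_true(is.na(h[1]))
  expect_equal(h[2], 0)
  expect_true(all(is.na(angularVelocity(tr)[1])))
})

test_that("|v_upwind| never exceeds v_ground on random walks", {
  set.seed(11)
  for (rep in 1:10) {
    tr <- Trajectory(x = 60 + cumsum(rnorm(50)), y = 25 + cumsum(rnorm(50)))
    vg <- groundSpeed(tr)
    vu <- upwindSpeed(tr, testArena())
    expect_true(all(abs(vu) <= vg + 1e-12))
  }
})

test_that("omega is translation invariant and flips under reflection", {
  set.seed(12)
  x <- 60 + cumsum(rnorm(40)); y <- 25 + cumsum(rnorm(40))
  om <- angularVelocity(Trajectory(x = x, y = y))
  omShift <- angularVelocity(Trajectory(x = x + 7, y = y - 4))
  omRefl <- angularVelocity(Trajectory(x = x, y = -y + 50))
  expect_equal(omShift, om, tolerance = 1e-9)
  expect_equal(omRefl, -om, tolerance = 1e-9)
})

test_that("sampled circle gives mean |omega| near 360/T", {
  nPer <- 600                      # samples per revolution
  tr <- circleTraj(nPerTurn = nPer, r = 10)
  period <- nPer * tr@dt
  om <- angularVelocity(tr)
  expect_equal(mean(abs(om), na.rm = TRUE), 360 / period,
               tolerance = 0.02)
})

test_that("direction to target follows the signed bearing convention", {
  target <- c(110, 25)
  # straight at the target: 0 everywhere
  toT <- Trajectory(x = seq(50, 109, by = 1), y = rep(25, 60))
  expect_equal(directionToTarget(toT, target), rep(0, 59))
  # straight away: 180
  away <- Trajectory(x = seq(100, 60, by = -1), y = rep(25, 41))
  expect_equal(abs(directionToTarget(away, target)), rep(180, 40))
  # perpendicular, left of the bearing: +90. Oracle: the movement vector
  # (0, 1) is the bearing vector (1, 0) rotated +90 deg counterclockwise.
  up <- Trajectory(x = c(60, 60), y = c(25, 26))
  expect_equal(directionToTarget(up, target)[1], 90)
  down <- Trajectory(x = c(60, 60), y = c(25, 24))
  expect_equal(directionToTarget(down, target)[1], -90)
  # standing on the target: missing
  onT <- Trajectory(x = c(110, 111), y = c(25, 25))
  expect_true(is.na(directionToTarget(onT, target)[1]))
})

test_that("direction histograms bin (-180, 180] and normalize", {
  h <- directionHistogram(rep(0, 50), nBins = 12)
  expect_equal(sum(h$fractions), 1)
  expect_equal(max(h$fractions), 1)
  # -170 and 170 land in opposite halves with 2 bins
  h2 <- directionHistogram(c(-170, 170), nBins = 2)
  expect_equal(h2$counts, c(1, 1))
  # boundary angles: 0 goes to the bin whose interval is (-x, 0]
  h3 <- directionHistogram(c(0), nBins = 2)
  expect_equal(h3$counts, c(1, 0))
  # 180 belongs to the last bin, -90 to the right-closed (-180, -90],
  # and NA inputs are excluded
  h4 <- directionHistogram(c(180, NA, -90), nBins = 4)
  expect_equal(h4$counts, c(1, 0, 0, 1))
  expect_equal(sum(h4$fractions), 1)
  set.seed(3)
  h5 <- directionHistogram(runif(100, -180, 180), nBins = 7)
  expect_equal(sum(h5$fractions), 1)
  expect_error(directionHistogram(1:3, nBins = 1), ">= 2")
})
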