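test_that("arrival detection finds the first crossing after onset", {
  pipe <- c(110, 25)
  # passes through the pipe 2 s after onset
  n <- 300
  tr <- Trajectory(x = seq(40, 40 + (n - 1) * 0.5, by = 0.5)[1:n],
                   y = rep(25, n), dt = 1 / 30)
  # x reaches 107 (within 3 cm) at sample 135 -> t = 134/30 = 4.4667
  arr <- arrivalTime(tr, pipe, captureRadiusCm = 3, onsetS = 2)
  expect_equal(arr, 134 / 30 - 2)
  # never within radius
  far <- Trajectory(x = rep(10, 60), y = rep(10, 60))
  expect_true(is.na(arrivalTime(far, pipe, 3, 1)))
  # already inside at onset: latency 0; oracle = first eligible sample
  near <- Trajectory(x = rep(109, 60), y = rep(25, 60))
  eligible <- which((0:59) / 30 >= 1)
  expect_equal(arrivalTime(near, pipe, 3, 1), (eligible[1] - 1) / 30 - 1)
  expect_equal(arrivalTime(near, pipe, 3, 1), 0)
})

test_that("latency groups partition arrivals exhaustively and disjointly", {
  expect_equal(assignGroup(2.0), "Under3")
  expect_equal(assignGroup(3.0), "Under3")     # boundary inclusive
  expect_equal(assignGroup(3.01), "Under10")
  expect_equal(assignGroup(10.0), "Under10")
  expect_equal(assignGroup(10.5), "Over10")
  expect_equal(assignGroup(NA_real_), "NoArrival")
  expect_error(assignGroup(-1), "negative")
  # every latency lands in exactly one group
  for (lat in seq(0, 25, by = 0.25))
    expect_length(assignGroup(lat), 1L)
})

test_that("per-second summaries bin [onset-3, onset+3) correctly", {
  tm <- seq(0.0, 9.99, by = 1 / 30)
  const <- rep(2.5, length(tm))
  s <- perSecondSummary(const, tm, onsetS = 5)
  expect_equal(nrow(s), 6L)
  expect_equal(s$mean, rep(2.5, 6))
  expect_equal(s$sd, rep(0, 6))
  expect_equal(s$bin_start, 2:7)

  # linear ramp values = t: bin means are the bin centers, 1.0 apart
  ramp <- perSecondSummary(tm, tm, onsetS = 5)
  expect_equal(diff(ramp$mean), rep(1, 5), tolerance = 1e-9)

  expect_error(perSecondSummary(const, tm, onsetS = 9),
               "window exceeds recording")
})

test_that("Mann-Whitney U matches the permutation oracle over all small splits", {
  # complete separation: U = 0
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(statistic(r), 0)
  # brute-force pairwise count oracle
  uBrute <- sum(outer(c(1, 2, 3), c(4, 5, 6), ">")) +
    0.5 * sum(outer(c(1, 2, 3), c(4, 5, 6), "=="))
  expect_equal(statistic(r), uBrute)

  # identical samples: p = 1 by symmetry
  expect_equal(pValue(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))), 1)

  # exact p equals full enumeration for every split with n_a + n_b <= 10
  set.seed(17)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      vals <- sample(seq_len(200), na + nb)   # tie-free
      a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
      expect_equal(pValue(mannWhitneyU(a, b)), mwuPermOracle(a, b),
                   tolerance = 1e-12,
                   info = sprintf("na=%d nb=%d", na, nb))
    }
  }
  expect_error(mannWhitneyU(numeric(0), 1:3), "empty sample")
})

test_that("U statistics are complementary and rank-invariant", {
  set.seed(19)
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(11)
    ua <- statistic(mannWhitneyU(a, b))
    ub <- statistic(mannWhitneyU(b, a))
    expect_equal(ua + ub, length(a) * length(b))
    # strictly monotone transform leaves U and p unchanged
    r1 <- mannWhitneyU(exp(a), exp(b))
    expect_equal(statistic(r1), ua)
    expect_equal(pValue(r1), pValue(mannWhitneyU(a, b)))
  }
})

test_that("Friedman statistic matches closed forms and stats::friedman.test", {
  # identical ranking in all blocks, k=3, n=6: statistic 12
  y <- matrix(rep(c(1.2, 3.4, 5.6), each = 6), nrow = 6)
  r <- friedmanTest(y)
  expect_equal(statistic(r), 12)
  # closed form: 12*n*sum((meanRank - (k+1)/2)^2)/(k*(k+1)) for no ties
  n <- 6; k <- 3
  closed <- 12 * n * sum((c(1, 2, 3) - 2)^2) / (k * (k + 1))
  expect_equal(statistic(r), closed)

  # identical treatments within every block: statistic 0, p 1
  flat <- matrix(rep(c(7, 7, 7), 4), nrow = 4, byrow = TRUE)
  rf <- friedmanTest(flat)
  expect_equal(statistic(rf), 0)
  expect_equal(pValue(rf), 1)

  # agreement with the reference implementation, with and without ties
  set.seed(23)
  for (rep in 1:8) {
    m <- matrix(sample(1:5, 15, replace = TRUE), nrow = 5)
    if (length(unique(as.vector(m))) == 1) next
    ours <- friedmanTest(m)
    ref <- stats::friedman.test(m)
    if (is.finite(ref$statistic)) {
      expect_equal(statistic(ours), unname(ref$statistic), tolerance = 1e-9)
      expect_equal(pValue(ours), ref$p.value, tolerance = 1e-9)
    }
  }
  expect_error(friedmanTest(matrix(c(1, NA, 2, 3), 2)), "missing cells")
})

test_that("Friedman exact p equals the within-block permutation oracle", {
  set.seed(29)
  for (rep in 1:3) {
    y <- matrix(rnorm(9), nrow = 3)           # k=3, n=3: 216 permutations
    pExact <- pValue(friedmanTest(y, method = "exact"))
    expect_equal(pExact, friedmanPermOracle(y), tolerance = 1e-9)
  }
  y4 <- matrix(rnorm(12), nrow = 4)           # k=3, n=4: 1296 permutations
  expect_equal(pValue(friedmanTest(y4, method = "exact")),
               friedmanPermOracle(y4), tolerance = 1e-9)
})

test_that("Friedman exact and asymptotic p agree in the rejection tail", {
  # mid-range p-values differ substantially at n = 6 because the exact
  # distribution is coarsely discrete there; in the decision-relevant tail
  # (asymptotic p < 0.05) the two routes agree closely
  set.seed(31)
  nTail <- 0
  for (rep in 1:40) {
    eff <- runif(1, 0, 2)
    y <- matrix(rnorm(18), nrow = 6) +
      matrix(rep(c(0, eff, 2 * eff), each = 6), nrow = 6)
    pe <- pValue(friedmanTest(y, method = "exact"))
    pa <- pValue(friedmanTest(y, method = "asymptotic"))
    expect_lt(abs(pe - pa), 0.15)
    if (pa < 0.05) {
      nTail <- nTail + 1
      expect_lt(abs(pe - pa), 0.02)
    }
  }
  expect_gte(nTail, 5)
})

test_that("inside/outside comparison partitions by step start position", {
  p <- SimParams(durationS = 30)
  mask <- simulatePlume(p)$mask
  trials <- simulateTrialSet(6, mix = c(Under3 = 1, Under10 = 0, Over10 = 0),
                             params = p, seed = 41)
  arrived <- Filter(function(tr) !is.na(tr@arrivalS), trials)
  expect_gte(length(arrived), 4)
  res <- insideOutsideComparison(arrived[[1]], mask)
  if (!res$insufficient) {
    expect_s4_class(res$turning, "TestResult")
    expect_equal(res$turning@method, "mann_whitney_u")
    samp <- insideOutsideSamples(arrived[[1]], mask)
    expect_equal(res$nInside, sum(samp$inside))
    expect_lte(max(samp$t), arrived[[1]]@onsetS + arrived[[1]]@arrivalS)
    expect_gte(min(samp$t), arrived[[1]]@onsetS + arrived[[1]]@arrivalS - 3)
  }
  # all samples on one side: flagged insufficient
  allIn <- new("PlumeMask", grid = matrix(TRUE, 20, 56), resolutionCm = 2.5,
               sourceXY = c(110, 25))
  resIn <- insideOutsideComparison(arrived[[1]], allIn)
  expect_true(resIn$insufficient)
  expect_null(resIn$ground)
  # no arrival: error
  clean <- simulateTrialSet(0, params = p, seed = 43, nClean = 1)[[1]]
  if (is.na(clean@arrivalS)) {
    expect_error(insideOutsideComparison(clean, mask), "no arrival")
  }
})

test_that("null inside/outside labels give uniform-ish p-values", {
  # identical kinematics in and out: rejection rate compatible with 0.05
  set.seed(47)
  nrep <- 400
  rej <- logical(nrep)
  for (i in seq_len(nrep)) {
    a <- rnorm(30); b <- rnorm(30)
    rej[i] <- pValue(mannWhitneyU(a, b)) < 0.05
  }
  ci <- 1.96 * sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(mean(rej) - 0.05), ci + 0.01)
})
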