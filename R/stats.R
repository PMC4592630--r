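#' Onset-to-arrival latency at the odor pipe
#'
#' First time at or after the stimulus onset at which the bee comes within
#' \code{captureRadiusCm} of the pipe, minus the onset; NA if it never does.
#' "Arrival" is not sharply defined by a point pipe, so the capture radius
#' (3 cm by default) is configurable.
#'
#' @param traj a [Trajectory-class].
#' @param pipeXY pipe position c(x, y) in cm.
#' @param captureRadiusCm capture radius (> 0).
#' @param onsetS stimulus onset time (s).
#' @return latency in s, or NA_real_.
#' @export
arrivalTime <- function(traj, pipeXY, captureRadiusCm = 3, onsetS = 5) {
  if (captureRadiusCm <= 0) stop("captureRadiusCm must be > 0")
  sel <- which(traj@t >= onsetS & !is.na(traj@x) & !is.na(traj@y))
  if (length(sel) == 0L) return(NA_real_)
  d <- sqrt((traj@x[sel] - pipeXY[1])^2 + (traj@y[sel] - pipeXY[2])^2)
  hit <- which(d <= captureRadiusCm)
  if (length(hit) == 0L) return(NA_real_)
  traj@t[sel[hit[1L]]] - onsetS
}

#' Latency group of a trial
#'
#' Arrival within 3 s of onset is Under3, within 10 s Under10, later
#' Over10; bees that never arrive are NoArrival. Boundaries are inclusive
#' on the right (a 3.0-s latency is Under3), so every latency has exactly
#' one group.
#'
#' @param arrivalS latency in s, or NA.
#' @return one of "Under3", "Under10", "Over10", "NoArrival".
#' @export
assignGroup <- function(arrivalS) {
  if (is.na(arrivalS)) return("NoArrival")
  if (arrivalS < 0) stop("negative latency")
  if (arrivalS <= 3) "Under3" else if (arrivalS <= 10) "Under10" else "Over10"
}

#' Per-second summaries around the stimulus onset
#'
#' Mean and SD of a kinematic series in each one-second bin of the window
#' [onset - beforeS, onset + afterS), the layout of the before/after
#' time-course comparison (3 s either side, tested per second with the
#' Friedman test).
#'
#' @param values numeric series (e.g. a [KinematicsSeries-class] field).
#' @param tMid time stamps of \code{values} (s).
#' @param onsetS stimulus onset (s).
#' @param beforeS,afterS window half-widths in whole seconds.
#' @return data.frame with bin_start, bin_end, n, mean, sd, empty; bins
#'   with no samples have NA mean/sd and empty = TRUE.
#' @export
perSecondSummary <- function(values, tMid, onsetS, beforeS = 3, afterS = 3) {
  if (length(values) != length(tMid)) stop("values and tMid lengths differ")
  if (onsetS - beforeS < min(tMid) - 1e-9 ||
      onsetS + afterS > max(tMid) + 1e-9)
    stop("window exceeds recording")
  starts <- onsetS - beforeS + seq_len(beforeS + afterS) - 1
  out <- lapply(starts, function(s) {
    sel <- tMid >= s & tMid < s + 1 & !is.na(values)
    n <- sum(sel)
    data.frame(bin_start = s, bin_end = s + 1, n = n,
               mean = if (n) mean(values[sel]) else NA_real_,
               sd = if (n > 1) stats::sd(values[sel]) else
                 if (n == 1) 0 else NA_real_,
               empty = n == 0L)
  })
  do.call(rbind, out)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The U
#' statistic uses midranks for ties; the p-value is exact when
#' n_a + n_b <= 12 and the pooled sample is tie-free, and otherwise uses
#' the normal approximation with tie and continuity corrections (both via
#' [stats::wilcox.test()]).
#'
#' @param a,b numeric samples (each non-empty).
#' @return A [TestResult-class]; \code{statistic} is U for sample \code{a}.
#' @export
mannWhitneyU <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  exact <- (na + nb <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  u <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
  new("TestResult", statistic = u, pValue = unname(wt$p.value),
      method = "mann_whitney_u", n = c(na, nb))
}

# tie-corrected Friedman chi-square from a block x treatment rank matrix
friedmanStatistic <- function(r, tieA) {
  n <- nrow(r); k <- ncol(r)
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - tieA / (k - 1)
  if (den <= 0) return(0)
  num / den
}

#' Friedman rank test for correlated samples
#'
#' Within-block midranks with the tie-corrected chi-square statistic;
#' asymptotic p from the chi-square distribution with k - 1 df, or (for
#' small designs, k <= 3 and n <= 6) an exact p by enumerating all (k!)^n
#' within-block permutations.
#'
#' @param y numeric matrix, rows = blocks (n), columns = treatments (k);
#'   no missing cells (listwise deletion is performed upstream).
#' @param method "asymptotic" (default) or "exact".
#' @return A [TestResult-class] with \code{n = c(k, n)}.
#' @export
friedmanTest <- function(y, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  y <- as.matrix(y)
  if (anyNA(y)) stop("missing cells")
  n <- nrow(y); k <- ncol(y)
  if (k < 2 || n < 2) stop("need k >= 2 treatments and n >= 2 blocks")
  r <- t(apply(y, 1L, rank))
  tieA <- sum(unlist(apply(y, 1L, function(row) {
    tt <- table(row); tt^3 - tt
  })))
  stat <- friedmanStatistic(r, tieA)
  if (method == "asymptotic") {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  } else {
    if (k > 3 || n > 6)
      stop("exact enumeration available only for k <= 3, n <= 6")
    perms <- permutationsOf(k)                   # k! x k index matrix
    # per block: its rank row under every within-block permutation
    blockRanks <- lapply(seq_len(n), function(b)
      matrix(r[b, perms], nrow = nrow(perms)))
    grid <- as.matrix(do.call(expand.grid,
                              rep(list(seq_len(nrow(perms))), n)))
    colS <- matrix(0, nrow(grid), k)
    for (b in seq_len(n)) colS <- colS + blockRanks[[b]][grid[, b], ]
    den <- n * k * (k + 1) - tieA / (k - 1)
    stats <- if (den <= 0) rep(0, nrow(grid)) else
      12 * rowSums((colS - n * (k + 1) / 2)^2) / den
    p <- mean(stats >= stat - 1e-9)
  }
  p <- min(max(p, 0), 1)
  new("TestResult", statistic = stat, pValue = p, method = "friedman",
      n = c(k, n))
}

# all permutations of 1..k as a k! x k matrix
permutationsOf <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(k - 1L)
  out <- do.call(rbind, lapply(seq_len(k), function(pos) {
    left <- if (pos > 1L) sub[, seq_len(pos - 1L), drop = FALSE] else NULL
    right <- if (pos < k) sub[, pos:(k - 1L), drop = FALSE] else NULL
    cbind(left, k, right)
  }))
  unname(out)
}

#' Inside/outside-plume comparison of flight indexes
#'
#' For the last \code{windowS} seconds before arrival at the odor source,
#' steps are partitioned by whether their start position lies inside the
#' plume mask (a step straddling the border is not split), and ground speed
#' and |angular velocity| are compared between the partitions with
#' two-sided Mann-Whitney U tests. The trajectory is smoothed with the
#' standard 5-point filter before kinematics.
#'
#' @param trial a [Trial-class] with an arrival.
#' @param mask a [PlumeMask-class].
#' @param windowS window length before arrival (s).
#' @param smoothWindow moving-average window for the kinematics.
#' @return list with \code{ground} and \code{turning} ([TestResult-class]
#'   or NULL), \code{nInside}, \code{nOutside}, and \code{insufficient}
#'   (TRUE when either partition is empty).
#' @export
insideOutsideComparison <- function(trial, mask, windowS = 3,
                                    smoothWindow = 5) {
  if (is.na(trial@arrivalS)) stop("trial has no arrival")
  parts <- insideOutsideSamples(trial, mask, windowS, smoothWindow)
  nIn <- sum(parts$inside, na.rm = TRUE)
  nOut <- sum(!parts$inside, na.rm = TRUE)
  if (nIn == 0L || nOut == 0L)
    return(list(ground = NULL, turning = NULL, nInside = nIn,
                nOutside = nOut, insufficient = TRUE))
  list(ground = mannWhitneyU(parts$vGround[parts$inside],
                             parts$vGround[!parts$inside]),
       turning = mannWhitneyU(parts$omegaAbs[parts$inside],
                              parts$omegaAbs[!parts$inside]),
       nInside = nIn, nOutside = nOut, insufficient = FALSE)
}

#' Per-step samples for the inside/outside comparison
#'
#' Returns, for each step starting in the pre-arrival window, the ground
#' speed, |angular velocity| and plume membership of the step's start
#' position — the raw material of [insideOutsideComparison()], exposed so
#' that samples can be pooled across trials.
#'
#' @inheritParams insideOutsideComparison
#' @return data.frame with t, vGround, omegaAbs, inside.
#' @export
insideOutsideSamples <- function(trial, mask, windowS = 3,
                                 smoothWindow = 5) {
  if (is.na(trial@arrivalS)) stop("trial has no arrival")
  arrivalAbs <- trial@onsetS + trial@arrivalS
  sm <- smoothTrajectory(trial@trajectory, smoothWindow)
  n <- length(sm@t)
  vg <- groundSpeed(sm)
  om <- abs(angularVelocity(sm))
  tStart <- sm@t[-n]
  sel <- which(tStart >= arrivalAbs - windowS & tStart < arrivalAbs &
                 !is.na(vg) & !is.na(om))
  inside <- pointsInPlume(mask, sm@x[sel], sm@y[sel])
  keep <- !is.na(inside)
  data.frame(t = tStart[sel][keep], vGround = vg[sel][keep],
             omegaAbs = om[sel][keep], inside = as.logical(inside[keep]))
}
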