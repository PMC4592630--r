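#' Estimate the static background of a frame sequence
#'
#' Per-pixel temporal median over the supplied frames. The median is robust
#' to the transient bee, which darkens any one pixel in well under half of
#' the frames of a search flight.
#'
#' @param fs a [FrameSequence-class].
#' @param maxFrames use at most this many evenly spaced frames (all by
#'   default); long recordings gain nothing from more than ~100 frames.
#' @return numeric matrix, same dimensions as the frames.
#' @export
estimateBackground <- function(fs, maxFrames = Inf) {
  stopifnot(is(fs, "FrameSequence"))
  fr <- frames(fs)
  if (length(fr) == 0L) stop("no frames")
  if (length(fr) > maxFrames)
    fr <- fr[unique(round(seq(1, length(fr), length.out = maxFrames)))]
  if (length(fr) == 1L) return(fr[[1L]])
  d <- dim(fr[[1L]])
  stack <- matrix(unlist(fr, use.names = FALSE), nrow = prod(d))
  med <- apply(stack, 1L, stats::median.default)
  matrix(med, nrow = d[1L], ncol = d[2L])
}

# 8-connected components among foreground pixels given as (row, col) pairs.
# Returns an integer label per pixel. BFS over a hashed coordinate set; the
# foreground is small (the bee is tens of pixels), so this is cheap.
labelComponents8 <- function(rows, cols, dims) {
  npx <- length(rows)
  lin <- (cols - 1L) * dims[1L] + rows          # column-major linear index
  pos <- integer(0)
  lookup <- new.env(hash = TRUE, size = max(16L, npx))
  for (i in seq_len(npx)) assign(as.character(lin[i]), i, envir = lookup)
  labels <- integer(npx)
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  current <- 0L
  for (i in seq_len(npx)) {
    if (labels[i] != 0L) next
    current <- current + 1L
    queue <- i
    labels[i] <- current
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(nb))) {
        r2 <- rows[j] + nb$dr[k]; c2 <- cols[j] + nb$dc[k]
        if (r2 < 1L || c2 < 1L || r2 > dims[1L] || c2 > dims[2L]) next
        key <- as.character((c2 - 1L) * dims[1L] + r2)
        m <- lookup[[key]]
        if (!is.null(m) && labels[m] == 0L) {
          labels[m] <- current
          queue <- c(queue, m)
        }
      }
    }
  }
  labels
}

#' Locate the bee in one frame
#'
#' Binarizes |frame - background| above \code{diffThreshold}, keeps
#' 8-connected components of at least \code{minBlobPx} pixels, and returns
#' the unweighted centroid (mean pixel coordinates, 0-based, x = column,
#' y = row) of the largest surviving component, or NULL when none survives.
#' An area tie is broken toward the component whose centroid is nearest the
#' previous detection, or the first in scan order when there is none.
#'
#' @param frame,background numeric matrices of identical dimensions
#'   (intensity 0--255).
#' @param params a [DetectionParams-class].
#' @param prev previous detection c(x, y) in pixels, or NULL.
#' @return c(x, y) in 0-based pixel coordinates, or NULL.
#' @export
locateBee <- function(frame, background, params = DetectionParams(),
                      prev = NULL) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background dimensions differ")
  fg <- abs(frame - background) > params@diffThreshold
  idx <- which(fg)
  if (length(idx) == 0L) return(NULL)
  d <- dim(frame)
  rows <- ((idx - 1L) %% d[1L]) + 1L
  cols <- ((idx - 1L) %/% d[1L]) + 1L
  labels <- labelComponents8(rows, cols, d)
  areas <- tabulate(labels)
  keep <- which(areas >= params@minBlobPx)
  if (length(keep) == 0L) return(NULL)
  best <- keep[areas[keep] == max(areas[keep])]
  if (length(best) > 1L) {
    cents <- vapply(best, function(l)
      c(mean(cols[labels == l]) - 1, mean(rows[labels == l]) - 1), numeric(2))
    if (!is.null(prev)) {
      dist2 <- colSums((cents - prev)^2)
      best <- best[which.min(dist2)]
    } else {
      best <- best[which.min(vapply(best, function(l)
        min(idx[labels == l]), numeric(1)))]
    }
  }
  sel <- labels == best[1L]
  c(x = mean(cols[sel]) - 1, y = mean(rows[sel]) - 1)
}

# pixel (0-based, continuous) <-> arena cm; pixel centers sit at
# (k + 0.5) / pxPerCm
pxToCm <- function(px, cal) (px + 0.5) / cal@pxPerCm
cmToPx <- function(cm, cal) cm * cal@pxPerCm - 0.5

#' Build a trajectory from a frame sequence
#'
#' Runs [locateBee()] on every frame against a median background, converts
#' detections to arena cm, and bridges detection gaps of at most
#' \code{maxGapFrames} consecutive misses by linear interpolation (flagged
#' \code{valid = FALSE}); longer gaps are kept as missing positions.
#'
#' @param fs a [FrameSequence-class].
#' @param cal an [ArenaCalibration-class].
#' @param params a [DetectionParams-class].
#' @param background optional precomputed background matrix; by default the
#'   temporal median of up to 101 evenly spaced frames.
#' @return A [Trajectory-class].
#' @export
buildTrajectory <- function(fs, cal = ArenaCalibration(),
                            params = DetectionParams(), background = NULL) {
  stopifnot(is(fs, "FrameSequence"))
  if (is.null(background)) background <- estimateBackground(fs, maxFrames = 101)
  fr <- frames(fs)
  n <- length(fr)
  x <- y <- rep(NA_real_, n)
  prev <- NULL
  for (i in seq_len(n)) {
    p <- locateBee(fr[[i]], background, params, prev = prev)
    if (!is.null(p)) {
      x[i] <- pxToCm(p[["x"]], cal)
      y[i] <- pxToCm(p[["y"]], cal)
      prev <- p
    }
  }
  detected <- !is.na(x)
  if (!any(detected)) stop("no bee detected")
  valid <- detected
  # bridge short gaps between detections
  det <- which(detected)
  if (length(det) > 1L) {
    for (k in seq_len(length(det) - 1L)) {
      gap <- det[k + 1L] - det[k] - 1L
      if (gap >= 1L && gap <= params@maxGapFrames) {
        ii <- (det[k] + 1L):(det[k + 1L] - 1L)
        w <- (ii - det[k]) / (det[k + 1L] - det[k])
        x[ii] <- x[det[k]] + w * (x[det[k + 1L]] - x[det[k]])
        y[ii] <- y[det[k]] + w * (y[det[k + 1L]] - y[det[k]])
      }
    }
  }
  Trajectory(x = x, y = y, t = (seq_len(n) - 1) / fps(fs), dt = 1 / fps(fs),
             valid = valid)
}

#' Smooth a trajectory with a centered moving average
#'
#' x and y are independently replaced by centered moving averages over
#' \code{window} samples; at the series ends the window shrinks
#' symmetrically (3-point at the second sample, 1-point at the first, for
#' the default 5-point filter). Time stamps are unchanged. Around missing
#' positions the window also shrinks symmetrically so that no NA enters an
#' average; samples that are themselves missing stay missing.
#'
#' @param traj a [Trajectory-class].
#' @param window odd window length (5 as in the analysis pipeline).
#' @return A smoothed [Trajectory-class].
#' @export
smoothTrajectory <- function(traj, window = 5) {
  stopifnot(is(traj, "Trajectory"))
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  h <- (window - 1) / 2
  n <- length(traj@t)
  sx <- traj@x
  sy <- traj@y
  ok <- !is.na(traj@x) & !is.na(traj@y)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    k <- min(h, i - 1, n - i)
    while (k > 0 && !all(ok[(i - k):(i + k)])) k <- k - 1
    if (k > 0) {
      sel <- (i - k):(i + k)
      sx[i] <- mean(traj@x[sel])
      sy[i] <- mean(traj@y[sel])
    }
  }
  Trajectory(x = sx, y = sy, t = traj@t, dt = traj@dt, valid = traj@valid)
}
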