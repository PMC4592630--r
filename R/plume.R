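# half-open spatial binning: cell k (1-based) covers [(k-1) bin, k bin);
# a point exactly on the top boundary of the grid joins the last cell
binIndex <- function(v, bin, n) {
  idx <- floor(v / bin) + 1
  idx[!is.na(v) & idx == n + 1 & abs(v - n * bin) < 1e-9] <- n
  idx
}

#' Extract a smoke (or bee) mask from one frame
#'
#' Pixel-wise thresholded background subtraction. Smoke is brighter than the
#' black-papered background used during the airflow visualization, so the
#' default polarity keeps pixels where frame - background exceeds the
#' threshold; the bee on white plywood is the opposite contrast
#' (\code{polarity = "dark"}).
#'
#' @param frame,background numeric matrices of identical dimensions.
#' @param threshold intensity threshold (0--255 scale).
#' @param polarity "bright" (smoke on dark) or "dark" (bee on white).
#' @return logical matrix, TRUE where the signal exceeds the threshold.
#' @export
extractSmokeMask <- function(frame, background, threshold = 40,
                             polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!identical(dim(frame), dim(background)))
    stop("frame and background dimensions differ")
  diffImg <- frame - background
  if (polarity == "dark") diffImg <- -diffImg
  diffImg > threshold
}

#' Superimpose smoke masks into an odor-spread-area mask
#'
#' Pixel-wise union of all masks, regridded onto the arena grid: a cell is
#' inside the plume iff any pixel whose center falls in that cell is TRUE
#' in any frame. This reproduces the static odor spread area obtained by
#' superimposing the per-frame smoke images.
#'
#' @param masks list of logical matrices (identical dimensions).
#' @param cal an [ArenaCalibration-class] (pixel scale and arena extents).
#' @param resolutionCm grid cell edge (2.5 cm by default, matching the
#'   occupancy maps for direct overlay).
#' @param sourceXY odor-source position in cm (defaults to the calibrated
#'   pipe position).
#' @return A [PlumeMask-class].
#' @export
superimposeMasks <- function(masks, cal = ArenaCalibration(),
                             resolutionCm = 2.5, sourceXY = NULL) {
  if (length(masks) == 0L) stop("need at least one mask")
  d <- dim(masks[[1L]])
  u <- masks[[1L]]
  for (m in masks[-1L]) {
    if (!identical(dim(m), d)) stop("inconsistent mask size")
    u <- u | m
  }
  nCols <- round(cal@arenaLengthCm / resolutionCm)
  nRows <- round(cal@arenaWidthCm / resolutionCm)
  grid <- matrix(FALSE, nrow = nRows, ncol = nCols)
  idx <- which(u)
  if (length(idx)) {
    pr <- ((idx - 1L) %% d[1L])        # 0-based pixel row
    pc <- ((idx - 1L) %/% d[1L])       # 0-based pixel col
    xs <- pxToCm(pc, cal)
    ys <- pxToCm(pr, cal)
    ci <- binIndex(ys, resolutionCm, nRows)
    cj <- binIndex(xs, resolutionCm, nCols)
    keep <- ci >= 1 & ci <= nRows & cj >= 1 & cj <= nCols
    grid[cbind(ci[keep], cj[keep])] <- TRUE
  }
  if (is.null(sourceXY)) sourceXY <- cal@pipeXY
  new("PlumeMask", grid = grid, resolutionCm = resolutionCm,
      sourceXY = as.numeric(sourceXY))
}

#' Is a point inside the odor spread area?
#'
#' Cell membership uses half-open intervals [k res, (k+1) res), so a point
#' on a cell boundary belongs to the higher-index cell.
#'
#' @param mask a [PlumeMask-class].
#' @param p c(x, y) in cm; must lie within the arena covered by the mask.
#' @return logical.
#' @export
pointInPlume <- function(mask, p) {
  nRows <- nrow(mask@grid)
  nCols <- ncol(mask@grid)
  res <- mask@resolutionCm
  if (is.na(p[1]) || is.na(p[2]) ||
      p[1] < 0 || p[1] > nCols * res + 1e-9 ||
      p[2] < 0 || p[2] > nRows * res + 1e-9)
    stop("point outside arena bounds")
  i <- binIndex(p[2], res, nRows)
  j <- binIndex(p[1], res, nCols)
  mask@grid[i, j]
}

# vectorized membership for internal use; points must be in bounds
pointsInPlume <- function(mask, x, y) {
  i <- binIndex(y, mask@resolutionCm, nrow(mask@grid))
  j <- binIndex(x, mask@resolutionCm, ncol(mask@grid))
  out <- rep(NA, length(x))
  ok <- !is.na(i) & !is.na(j) & i >= 1 & i <= nrow(mask@grid) &
    j >= 1 & j <= ncol(mask@grid)
  out[ok] <- mask@grid[cbind(i[ok], j[ok])]
  out
}

#' Write / read a plume mask as a 0/1 CSV matrix
#'
#' @param mask a [PlumeMask-class].
#' @param path CSV file.
#' @return invisibly \code{path}; for the reader, a [PlumeMask-class].
#' @export
writePlumeCSV <- function(mask, path) {
  utils::write.table(mask@grid * 1L, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writePlumeCSV
#' @param resolutionCm,sourceXY grid metadata (not stored in the CSV).
#' @export
readPlumeCSV <- function(path, resolutionCm = 2.5, sourceXY = c(110, 25)) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  new("PlumeMask", grid = m > 0, resolutionCm = resolutionCm,
      sourceXY = as.numeric(sourceXY))
}
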