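#' Read a directory of image frames
#'
#' Reads BMP/PNG frames (the recordings were exported as bitmap sequences),
#' ordered lexicographically by filename so frame order is deterministic for
#' a fixed set of names. Color images are converted to grayscale by the
#' unweighted channel mean: the arena is white plywood under white LEDs, so
#' chroma carries no signal.
#'
#' @param path directory containing the frames.
#' @param fps frames per second of the recording (30 for the study camera).
#' @param pattern filename regexp; defaults to BMP/PNG extensions.
#' @return A [FrameSequence-class].
#' @export
readFrameDir <- function(path, fps = 30,
                         pattern = "\\.(bmp|png)$") {
  if (!dir.exists(path)) stop("no frames: directory not found: ", path)
  files <- sort(list.files(path, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frames in directory: ", path)
  mats <- lapply(files, readGrayImage)
  d <- dim(mats[[1L]])
  for (m in mats)
    if (!identical(dim(m), d)) stop("inconsistent frame size")
  FrameSequence(mats, fps = fps, origin = path)
}

#' Read one image file as a grayscale 0--255 matrix
#'
#' @param file path to a PNG or BMP file.
#' @return numeric matrix (rows = image rows), intensities 0--255.
#' @export
readGrayImage <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    a <- png::readPNG(file)
    if (length(dim(a)) == 3L) {
      nc <- min(dim(a)[3L], 3L)  # drop alpha, average RGB
      a <- apply(a[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
    }
    return(a * 255)
  }
  if (ext == "bmp") return(readBMP(file))
  stop("unsupported image format: ", file)
}

# Minimal uncompressed BMP reader (8-bit paletted and 24-bit BGR), since no
# installed reader handles BMP. Returns grayscale by unweighted channel mean.
readBMP <- function(file) {
  raw <- readBin(file, "raw", n = file.info(file)$size)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", file)
  le <- function(off, size) {  # little-endian unsigned int at 0-based offset
    sum(as.integer(raw[off + seq_len(size)]) * 256^(seq_len(size) - 1))
  }
  dataOffset <- le(10, 4)
  width <- le(18, 4)
  height <- le(22, 4)
  bottomUp <- TRUE
  if (height > 2^31 / 2) {  # negative height: top-down row order
    height <- 2^32 - height
    bottomUp <- FALSE
  }
  bpp <- le(28, 2)
  if (le(30, 4) != 0) stop("compressed BMP not supported: ", file)
  if (!bpp %in% c(8, 24)) stop("unsupported BMP bit depth: ", bpp)
  rowBytes <- ((width * bpp / 8 + 3) %/% 4) * 4
  img <- matrix(0, nrow = height, ncol = width)
  if (bpp == 8) {
    headerSize <- le(14, 4)
    nCol <- le(46, 4)
    if (nCol == 0) nCol <- 256
    pal <- matrix(as.integer(raw[14 + headerSize + seq_len(nCol * 4)]),
                  ncol = 4, byrow = TRUE)  # B, G, R, reserved
    gray <- rowMeans(pal[, 1:3, drop = FALSE])
  }
  for (r in seq_len(height)) {
    off <- dataOffset + (r - 1) * rowBytes
    rowIdx <- if (bottomUp) height - r + 1 else r
    if (bpp == 24) {
      px <- as.integer(raw[off + seq_len(3 * width)])
      bgr <- matrix(px, nrow = 3)
      img[rowIdx, ] <- colMeans(bgr)
    } else {
      idx <- as.integer(raw[off + seq_len(width)]) + 1L
      img[rowIdx, ] <- gray[idx]
    }
  }
  img
}

#' Write a frame sequence as numbered PNG files
#'
#' @param fs a [FrameSequence-class].
#' @param path output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the written file paths.
#' @export
writeFrameDir <- function(fs, path, prefix = "frame") {
  stopifnot(is(fs, "FrameSequence"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  fr <- frames(fs)
  files <- file.path(path, sprintf("%s_%05d.png", prefix, seq_along(fr) - 1L))
  for (i in seq_along(fr)) {
    m <- pmin(pmax(fr[[i]], 0), 255) / 255
    png::writePNG(m, files[i])
  }
  invisible(files)
}

#' Write / read a trajectory as CSV
#'
#' The file has the fixed header \code{frame,t_s,x_cm,y_cm} with one row per
#' sample; positions are in arena cm. Missing detections are empty cells.
#' A write-then-read round trip reproduces positions to 1e-6 cm. The
#' detection flag is not persisted: on read, \code{valid} is reconstructed
#' as "position present".
#'
#' @param traj a [Trajectory-class].
#' @param path output CSV file.
#' @return invisibly, \code{path}.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  df <- positions(traj)[, c("frame", "t_s", "x_cm", "y_cm")]
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @param dt sampling period override; by default inferred from the t column.
#' @return For \code{readTrajectoryCSV}, a [Trajectory-class].
#' @export
readTrajectoryCSV <- function(path, dt = NULL) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("frame", "t_s", "x_cm", "y_cm")
  if (!all(need %in% names(df)))
    stop("malformed header: expected columns ", paste(need, collapse = ","))
  for (cn in need) {
    v <- df[[cn]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad))
        stop(sprintf("parse error in column '%s' at data row %d: '%s'",
                     cn, bad[1], v[bad[1]]))
      v[v == ""] <- NA
      df[[cn]] <- as.numeric(v)
    }
  }
  if (nrow(df) == 0L) stop("empty trajectory file: ", path)
  if (nrow(df) > 1L && any(diff(df$t_s) <= 0)) stop("non-monotone time")
  if (is.null(dt))
    dt <- if (nrow(df) > 1L) stats::median(diff(df$t_s)) else 1 / 30
  Trajectory(x = df$x_cm, y = df$y_cm, t = df$t_s, dt = dt)
}

#' Read an analysis configuration file (YAML or JSON)
#'
#' The file holds the arena calibration, detection and smoke thresholds, and
#' stimulus metadata. Recognized blocks: \code{arena} (px_per_cm,
#' arena_length_cm, arena_width_cm, feeder_xy_cm, pipe_xy_cm, upwind_sign),
#' \code{detection} (diff_threshold, min_blob_px, max_gap_frames),
#' \code{smoke} (threshold), \code{stimulus} (onset_s, capture_radius_cm).
#' Missing entries fall back to the package defaults.
#'
#' @param path a .yaml/.yml or .json file.
#' @return list with elements \code{arena} ([ArenaCalibration-class]),
#'   \code{detection} ([DetectionParams-class]), \code{smoke},
#'   \code{stimulus}.
#' @export
readConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON: ", path)
  a <- cfg$arena
  get <- function(block, key, default) {
    v <- block[[key]]
    if (is.null(v)) default else unlist(v)
  }
  arena <- ArenaCalibration(
    pxPerCm = get(a, "px_per_cm", 640 / 140),
    arenaLengthCm = get(a, "arena_length_cm", 140),
    arenaWidthCm = get(a, "arena_width_cm", 50),
    feederXY = get(a, "feeder_xy_cm", c(60, 25)),
    pipeXY = get(a, "pipe_xy_cm", c(110, 25)),
    upwindSign = get(a, "upwind_sign", 1))
  d <- cfg$detection
  detection <- DetectionParams(
    diffThreshold = get(d, "diff_threshold", 40),
    minBlobPx = get(d, "min_blob_px", 6),
    maxGapFrames = get(d, "max_gap_frames", 5))
  list(arena = arena, detection = detection,
       smoke = list(threshold = get(cfg$smoke, "threshold", 40)),
       stimulus = list(onset_s = get(cfg$stimulus, "onset_s", 5),
                       capture_radius_cm =
                         get(cfg$stimulus, "capture_radius_cm", 3)))
}
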