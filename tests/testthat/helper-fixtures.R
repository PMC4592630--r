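# shared fixtures, built in code at test time

testArena <- function() ArenaCalibration()

linearTraj <- function(n = 10, x0 = 10, y0 = 25, dx = 1, dy = 0, dt = 1 / 30) {
  Trajectory(x = x0 + (0:(n - 1)) * dx, y = y0 + (0:(n - 1)) * dy, dt = dt)
}

circleTraj <- function(nPerTurn = 600, r = 10, center = c(70, 25),
                       nTurns = 1, dt = 1 / 30) {
  th <- 2 * pi * (0:(nPerTurn * nTurns)) / nPerTurn
  Trajectory(x = center[1] + r * cos(th), y = center[2] + r * sin(th), dt = dt)
}

# minimal uncompressed 24-bit BMP writer (test oracle for the reader)
writeTestBMP <- function(img, path) {
  h <- nrow(img); w <- ncol(img)
  rowBytes <- ((w * 3 + 3) %/% 4) * 4
  dataSize <- rowBytes * h
  le <- function(x, size) as.raw((x %/% 256^(0:(size - 1))) %% 256)
  header <- c(charToRaw("BM"), le(54 + dataSize, 4), le(0, 4), le(54, 4),
              le(40, 4), le(w, 4), le(h, 4), le(1, 2), le(24, 2), le(0, 4),
              le(dataSize, 4), le(2835, 4), le(2835, 4), le(0, 4), le(0, 4))
  px <- raw(dataSize)
  for (r in seq_len(h)) {       # bottom-up rows, BGR
    rowImg <- round(img[h - r + 1, ])
    off <- (r - 1) * rowBytes
    px[off + seq_len(3 * w)] <- as.raw(rep(rowImg, each = 3))
  }
  writeBin(c(header, px), path)
  invisible(path)
}

# Mann-Whitney permutation oracle: exact two-sided p by enumerating every
# assignment of the pooled values to groups of sizes n_a, n_b
mwuPermOracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  uOf <- function(idx) {
    sum(rank(pooled)[idx]) - na * (na + 1) / 2
  }
  mu <- na * length(b) / 2
  uObs <- uOf(seq_len(na))
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, uOf)
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

# Friedman permutation oracle: enumerate all within-block permutations,
# recompute the statistic with stats::friedman.test each time
friedmanPermOracle <- function(y) {
  k <- ncol(y); n <- nrow(y)
  statOf <- function(m) unname(stats::friedman.test(m)$statistic)
  obs <- statOf(y)
  perms <- asplit(permsOracle(k), 1)
  idx <- rep(list(seq_along(perms)), n)
  grid <- expand.grid(idx)
  stats <- apply(grid, 1, function(g) {
    m <- y
    for (b in seq_len(n)) m[b, ] <- y[b, perms[[g[b]]]]
    statOf(m)
  })
  mean(stats >= obs - 1e-9)
}

permsOracle <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permsOracle(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    t(apply(sub, 1, function(p) append(p, k, after = pos - 1)))
  }))
}
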