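# Independent oracles used to freeze expected values. Each is a direct,
# slow implementation kept deliberately separate from the package's own
# code paths.

# brute-force Euclidean distance transform: nearest background pixel by
# exhaustive search, image border treated as background
brute_force_edt <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  bg <- which(p == 0L, arr.ind = TRUE)
  d <- matrix(0, nr + 2L, nc + 2L)
  fg <- which(p == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    d[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  d[2:(nr + 1L), 2:(nc + 1L)]
}

# exhaustive-scan Otsu: maximize between-class variance over 256 candidate
# thresholds on [0, 1]
brute_force_otsu <- function(px) {
  cand <- (0:255) / 255
  best_t <- NA; best_v <- -1
  for (t in cand) {
    g1 <- px[px <= t]; g2 <- px[px > t]
    if (!length(g1) || !length(g2)) next
    w1 <- length(g1) / length(px); w2 <- 1 - w1
    v <- w1 * w2 * (mean(g1) - mean(g2))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# exact optimal 1-D k-means by dynamic programming (O(k n^2))
dp_kmeans_1d <- function(x, k) {
  x <- sort(x); n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {           # cost of segment x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n); split_at <- matrix(0L, k, n)
  for (i in 1:n) D[1, i] <- sse(1, i)
  for (j in 2:k) for (i in j:n) {
    costs <- vapply(j:i, function(m) D[j - 1, m - 1] + sse(m, i), numeric(1))
    D[j, i] <- min(costs)
    split_at[j, i] <- (j:i)[which.min(costs)]
  }
  # recover boundaries
  bounds <- integer(k + 1); bounds[k + 1] <- n
  i <- n
  for (j in k:2) { b <- split_at[j, i]; bounds[j] <- b - 1L; i <- b - 1L }
  bounds[1] <- 0L
  means <- vapply(1:k, function(j) mean(x[(bounds[j] + 1):bounds[j + 1]]),
                  numeric(1))
  list(means = means, sse = D[k, n])
}

# shortest foreground chord through (r, c) over the four principal
# directions (vertical, horizontal, both diagonals); diagonal steps count
# sqrt(2). A direction-free stand-in for the perpendicular width.
chord_width <- function(mask, r, c) {
  nr <- nrow(mask); nc <- ncol(mask)
  run <- function(dr, dc) {
    len <- 1L
    i <- r + dr; j <- c + dc
    while (i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j] == 1L) {
      len <- len + 1L; i <- i + dr; j <- j + dc
    }
    i <- r - dr; j <- c - dc
    while (i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j] == 1L) {
      len <- len + 1L; i <- i - dr; j <- j - dc
    }
    len
  }
  min(run(1, 0), run(0, 1), run(1, 1) * sqrt(2), run(1, -1) * sqrt(2))
}

# chord through a point perpendicular to a known direction, by sub-pixel
# marching until the mask is left on both sides (1-based continuous p0)
perp_chord <- function(mask, p0, dir) {
  nr <- nrow(mask); nc <- ncol(mask)
  nv <- c(-dir[2], dir[1]) / sqrt(sum(dir^2))
  march <- function(sgn) {
    t <- 0
    repeat {
      q <- round(p0 + sgn * (t + 0.25) * nv)
      if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc ||
          mask[q[1], q[2]] == 0L) break
      t <- t + 0.25
    }
    t
  }
  march(1) + march(-1) + 1
}

# small ready-made specs
ribbon_spec <- function(width = 11, shape = c(64, 128), noise = 0,
                        row = floor(shape[1] / 2) - 1) {
  fiber_spec(1, data.frame(mean = width, sd = 0, weight = 1),
             curvature = Inf, fiber_intensity = 0.8,
             background_intensity = 0.2,
             texture = list(noise_sd = noise, corr_len = 1.5),
             image_shape = shape, seed = 7, orientation = 0,
             start = c(row, 0), name = "ribbon")
}

quick_spec <- function(name, intensity = 0.8, width = 9, n = 12,
                       shape = c(448, 448), corr = 2, noise = 0.05,
                       bg = 0.1) {
  fiber_spec(n, data.frame(mean = width, sd = 2, weight = 1),
             curvature = 150, fiber_intensity = intensity,
             background_intensity = bg,
             texture = list(noise_sd = noise, corr_len = corr),
             image_shape = shape, name = name)
}
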