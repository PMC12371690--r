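# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp into [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# draw a sub-seed stream deterministically from a master seed; keeps every
# derived seed a valid 32-bit integer
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# 8-neighbour count of a binary matrix (zero-padded borders)
neighbor_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  s <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    s <- s + p[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  s
}

# number of 8-connected foreground components (union-find over pixels)
count_components8 <- function(m) {
  idx <- which(m == 1L)
  n <- length(idx)
  if (n == 0L) return(0L)
  nr <- nrow(m)
  pos <- integer(length(m)); pos[idx] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  # look at half the neighbourhood; union-find symmetrizes
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- rows + d[1]; cc <- cols + d[2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(m)
    nb <- integer(n); nb[ok] <- pos[(cc[ok] - 1L) * nr + rr[ok]]
    for (i in which(nb > 0L)) {
      ri <- find(i); rj <- find(nb[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# round to the nearest odd integer, never below `min`
round_odd <- function(x, min = 3L) {
  o <- 2L * round((x - 1) / 2) + 1L
  pmax(as.integer(o), as.integer(min))
}

# mean +/- sd formatted the way width summaries are reported, e.g.
# "20 +/- 2 nm" or "17 +/- 0.5 nm": sd to one significant digit, mean to
# the same decimal place
format_mean_sd <- function(mean, sd, unit = "px") {
  sd1 <- signif(sd, 1)
  dec <- if (sd1 <= 0 || !is.finite(sd1)) 0L else max(0L, -floor(log10(sd1)))
  sprintf("%.*f ± %s %s", dec, round(mean, dec), format(sd1), unit)
}
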