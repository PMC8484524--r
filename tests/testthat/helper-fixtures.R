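# Small reusable fixtures and independent (brute-force) oracles.

toy_bold <- function(dims = c(6, 6, 6), T = 40, tr = 2, seed = 1) {
  set.seed(seed)
  bold_image(array(rnorm(prod(dims) * T), c(dims, T)), tr = tr)
}

# Pair of series with EXACT per-window sample correlations over
# non-overlapping windows (Gram-Schmidt construction).
exact_r_series <- function(rs, width) {
  x <- y <- numeric(0)
  for (r in rs) {
    e <- rnorm(width)
    u <- e - mean(e); u <- u / sqrt(sum(u^2))
    f <- rnorm(width)
    w <- f - mean(f) - sum(f * u) * u
    w <- w / sqrt(sum(w^2))
    x <- c(x, u)
    y <- c(y, r * u + sqrt(1 - r^2) * w)
  }
  list(x = x, y = y)
}

# Independent 26-connectivity labelling by breadth-first search in plain R.
label_brute <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    lab[s] <- nxt
    frontier <- s
    while (length(frontier)) {
      fresh <- integer(0)
      for (v in frontier) {
        ijk <- arrayInd(v, dims)
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          p <- ijk + c(dx, dy, dz)
          if (any(p < 1) || any(p > dims)) next
          u <- p[1] + dims[1] * ((p[2] - 1) + dims[2] * (p[3] - 1))
          if (mask[u] && lab[u] == 0L) {
            lab[u] <- nxt
            fresh <- c(fresh, u)
          }
        }
      }
      frontier <- fresh
    }
  }
  lab
}

# Discrete TFCE by direct summation over thresholds (the definition).
tfce_brute <- function(map, H = 2, E = 0.5, dh = max(map) / 100) {
  dims <- dim(map)
  if (is.null(dims)) {
    dims <- c(length(map), 1L, 1L)
    map <- array(map, dims)
  }
  out <- array(0, dims)
  K <- floor(max(map) / dh + 1e-9)
  for (k in seq_len(K)) {
    h <- k * dh
    lab <- label_brute(array(map >= h - 1e-12, dims))
    sizes <- tabulate(lab)
    sup <- lab > 0
    out[sup] <- out[sup] + sizes[lab[sup]]^E * h^H * dh
  }
  out
}
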