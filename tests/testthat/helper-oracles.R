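# Independent brute-force oracles used to freeze expected values.

# median via explicit order statistics (independent of stats::median)
brute_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  (s[ceiling(n / 2)] + s[floor(n / 2) + 1]) / 2
}

brute_mad <- function(x, scale = 1) {
  scale * brute_median(abs(x - brute_median(x)))
}

brute_z_prime <- function(sample, control, scale = 1) {
  1 - 3 * (brute_mad(sample, scale) + brute_mad(control, scale)) /
    abs(brute_median(sample) - brute_median(control))
}

# exhaustive-search intermeans threshold: the fixed point of
# t = (mean(x < t) + mean(x >= t)) / 2 located by scanning a fine grid
oracle_intermeans <- function(x, n_grid = 4001) {
  v <- as.numeric(x)
  grid <- seq(min(v), max(v), length.out = n_grid)
  f <- vapply(grid, function(t) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) return(NA_real_)
    t - (mean(lo) + mean(hi)) / 2
  }, numeric(1))
  grid[which.min(abs(f))]
}

# direct 3x3 median with zero-ignoring edge handling left to the caller:
# evaluates the median over the in-bounds neighbourhood values only when
# full = FALSE, or pads with the border value when full = TRUE
brute_median3 <- function(m) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    vals <- as.numeric(m[ii, jj])
    # replicate-pad to a full 9-neighbourhood at the borders
    vals <- c(vals, rep(m[i, j], 9 - length(vals)))
    out[i, j] <- brute_median(vals)
  }
  out
}

# render-and-count helpers
simple_disk <- function(h, w, cy, cx, r) {
  outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`) <= r^2
}
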