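# Independent oracles used across the suite. These are deliberately naive
# implementations kept separate from the package's code paths.

# Pair-counting adjusted Rand index: enumerate all C(n,2) pairs, count
# agreements, apply the adjusted-index identity.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- n * (n - 1) / 2
  expected <- (s11 + s10) * (s11 + s01) / np
  maxidx <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxidx == expected) return(if (s10 + s01 == 0) 1 else 0)
  (s11 - expected) / (maxidx - expected)
}

# Brute-force sliding-window maximum with reflected edges; window of size m
# spans offsets -floor((m-1)/2) .. ceil((m-1)/2) around each pixel.
max_filter_oracle <- function(x, size) {
  lo <- floor((size - 1) / 2)
  hi <- size - 1 - lo
  refl <- function(i, n) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
    i
  }
  out <- x
  for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
    rr <- refl((r - lo):(r + hi), nrow(x))
    cc <- refl((c - lo):(c + hi), ncol(x))
    out[r, c] <- max(x[rr, cc])
  }
  out
}

# A small honeycomb fixture: one centre spot with six equidistant ring spots.
honeycomb7 <- function(spacing = 100) {
  ang <- seq(0, 300, by = 60) * pi / 180
  coords <- rbind(c(0, 0), cbind(spacing * sin(ang), spacing * cos(ang)))
  colnames(coords) <- c("pixel_row", "pixel_col")
  coords
}

# Small simulated section shared by several files (cheap: ~1 s).
tiny_sim <- function(seed = 3, ...) {
  simulate_spots(n_rows = 8, n_cols = 10, n_genes = 60, seed = seed, ...)
}
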