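# Small in-code fixtures shared across test files.

# Two well-separated Gaussian clusters in D dimensions.
two_cluster_data <- function(n_per = 20, D = 4, sep = 10, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n_per * D, 0, sd), n_per, D)
    b <- matrix(rnorm(n_per * D, sep, sd), n_per, D)
    list(x = rbind(a, b),
         labels = rep(c("G1", "G2"), each = n_per))
  })
}

# A segment carrying a single unit sinusoid on one channel.
sinusoid_segment <- function(freq, n_channels = 1, channel = 1,
                             amplitude = 1, duration = 2, fs = 125) {
  tt <- (seq_len(duration * fs) - 1) / fs
  m <- matrix(0, n_channels, length(tt))
  m[channel, ] <- amplitude * sin(2 * pi * freq * tt)
  eeg_segment(m, sample_rate = fs)
}

# Fast schedule for module-level fits.
quick_schedule <- function(seed = 1, epochs = 25) {
  som_schedule(epochs = epochs, seed = seed)
}

# Independent scalar-loop oracles (kept deliberately naive).
oracle_distance <- function(x, m) {
  s <- 0
  for (j in seq_along(x)) s <- s + (x[j] - m[j])^2
  sqrt(s)
}

oracle_winner <- function(x, W, enabled) {
  best <- Inf; best_k <- NA_integer_
  for (k in seq_len(nrow(W))) {
    if (!enabled[k]) next
    d <- oracle_distance(x, W[k, ])
    if (d < best) { best <- d; best_k <- k }
  }
  best_k
}

oracle_update <- function(W, x, C, alpha, sigma, grid) {
  out <- W
  for (k in seq_len(nrow(W))) {
    d2 <- (grid[C, 1] - grid[k, 1])^2 + (grid[C, 2] - grid[k, 2])^2
    h <- alpha * exp(-d2 / sigma^2)
    for (j in seq_len(ncol(W)))
      out[k, j] <- W[k, j] + h * (x[j] - W[k, j])
  }
  out
}
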