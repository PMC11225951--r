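# shared helpers: small calibrations are expensive enough to cache per session
.cal_cache <- new.env(parent = emptyenv())

cached_calibration <- function(p, gamma, beta, n_runs, seed,
                               alpha = 0.05, l = 0) {
  key <- paste(p, gamma, beta, n_runs, seed, sep = "_")
  if (is.null(.cal_cache[[key]])) {
    grid <- scale_grid(p, beta)
    tn <- default_tuning(p, alpha = alpha, beta = beta, gamma = gamma, l = l)
    .cal_cache[[key]] <- calibrate_thresholds(p, gamma, tn, grid,
                                              n_runs = n_runs, seed = seed)
  }
  .cal_cache[[key]]
}

# independent brute-force statistics from the raw stream window
brute_diag_stat <- function(x, scales) {
  n <- nrow(x)
  best <- 0
  for (j in seq_len(ncol(x))) {
    cs <- c(0, cumsum(x[, j]))
    for (b in scales) {
      for (h in 0:n) {
        v <- b * (cs[n + 1] - cs[n + 1 - h]) - b^2 * h / 2
        if (v > best) best <- v
      }
    }
  }
  best
}

random_small_stream <- function(n, p, mu = 0) {
  x <- matrix(rnorm(n * p), n, p)
  if (mu != 0) x[, 1] <- x[, 1] + mu
  x
}
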