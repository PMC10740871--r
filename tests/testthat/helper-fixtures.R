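# Shared fixtures: small signals, clips and an independent brute-force MCC
# oracle (bandpass by explicit bin masking, then direct-summation circular
# cross-correlation over every lag of the padded grid -- no shared
# cross-spectrum code path with the implementation).

tone <- function(freq_hz, fs = 30, n = 300, phase = 0) {
  t <- (seq_len(n) - 1) / fs
  signal1d(sin(2 * pi * freq_hz * t + phase), fs)
}

# a random signal strictly band-limited to [f1, f2] on the length-n circular
# grid (constructed in the frequency domain, so it is exactly periodic)
narrowband <- function(n = 300, fs = 30, f1 = 0.8, f2 = 2.5) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * fs / n
  X[!(abs(f) >= f1 & abs(f) <= f2)] <- 0
  signal1d(Re(stats::fft(X, inverse = TRUE) / n), fs)
}

oracle_mcc <- function(y, yhat, band = hr_band()) {
  n <- length(y$values); fs <- y$fs
  yc <- y$values - mean(y$values)
  uc <- yhat$values - mean(yhat$values)
  L <- 2^ceiling(log2(2 * n))
  k <- 0:(L - 1)
  freq <- ifelse(k <= L / 2, k, k - L) * fs / L
  m <- abs(freq) >= band$f_lo & abs(freq) <= band$f_hi
  yb <- Re(stats::fft(m * stats::fft(c(yc, rep(0, L - n))), inverse = TRUE) / L)
  up <- c(uc, rep(0, L - n))
  best <- -Inf
  for (lag in 0:(L - 1)) {
    s <- sum(yb[((0:(L - 1) + lag) %% L) + 1] * up)
    if (s > best) best <- s
  }
  Y <- stats::fft(c(yc, rep(0, L - n)))
  py <- Mod(Y)^2
  cpr <- sum(py[m]) / sum(py[-1])
  cpr * best / (n * sqrt(mean(yc^2)) * sqrt(mean(uc^2)))
}

# tiny labeled clip batch for training-path tests
tiny_dataset <- function(n_train = 4, n_val = 2, t_frames = 64, fs = 30,
                         seed = 1) {
  make_dataset(n_train + n_val + 1,
               split = c(train = n_train, val = n_val, test = 1) /
                 (n_train + n_val + 1),
               duration_s = t_frames / fs, fs = fs, seed = seed)
}
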