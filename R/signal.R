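#' Uniformly sampled one-dimensional signal
#'
#' Container for a PPG waveform, a predicted rPPG waveform, or a spatially
#' pooled activation trace: a numeric vector plus its sampling rate.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @param fs sampling rate in Hz (> 0).
#' @return An object of class `signal1d` with fields `values` and `fs`.
#' @examples
#' s <- signal1d(sin(2 * pi * 1.2 * seq(0, 10, by = 1/30)), fs = 30)
#' length(s$values)
#' @export
signal1d <- function(values, fs) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("signal1d: need at least 2 samples, got ", length(values))
  if (!all(is.finite(values)))
    stop("signal1d: values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("signal1d: fs must be a single positive number")
  structure(list(values = values, fs = as.numeric(fs)), class = "signal1d")
}

#' @export
print.signal1d <- function(x, ...) {
  cat(sprintf("<signal1d: %d samples @ %g Hz (%.2f s)>\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' Heart-rate frequency band
#'
#' A passband in Hz. The default covers the conventional heart-rate range of
#' 40--180 beats per minute (0.667--3 Hz).
#'
#' @param f_lo,f_hi passband edges in Hz, `0 < f_lo < f_hi`.
#' @return An object of class `bandpass_spec`.
#' @export
hr_band <- function(f_lo = 40 / 60, f_hi = 180 / 60) {
  if (!(f_lo > 0 && f_hi > f_lo))
    stop("hr_band: need 0 < f_lo < f_hi")
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "bandpass_spec")
}

#' Remove the mean of a signal
#'
#' @param s a [signal1d].
#' @return A zero-mean `signal1d` of the same length and rate.
#' @export
mean_center <- function(s) {
  stopifnot(inherits(s, "signal1d"))
  signal1d(s$values - mean(s$values), s$fs)
}

#' Binary band-pass mask over FFT bins
#'
#' Marks every FFT bin (positive- and negative-frequency alike) whose absolute
#' frequency lies inside the band, so that a masked Hermitian spectrum
#' inverse-transforms to a real signal. The DC bin and any bin outside the
#' band are zero.
#'
#' @param n_fft number of FFT bins (>= 2).
#' @param fs sampling rate in Hz of the transformed signal.
#' @param band a [hr_band] passband; must satisfy `f_hi < fs/2`.
#' @return Numeric 0/1 vector of length `n_fft`.
#' @export
bandpass_mask <- function(n_fft, fs, band = hr_band()) {
  stopifnot(inherits(band, "bandpass_spec"))
  if (n_fft < 2L) stop("bandpass_mask: n_fft must be >= 2")
  if (band$f_hi >= fs / 2)
    stop("bandpass_mask: band upper edge ", band$f_hi,
         " Hz is not below the Nyquist rate ", fs / 2, " Hz")
  k <- 0:(n_fft - 1L)
  freq <- ifelse(k <= n_fft / 2, k, k - n_fft) * fs / n_fft
  as.numeric(abs(freq) >= band$f_lo & abs(freq) <= band$f_hi)
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

# Shared setup for the MCC value and its gradient: mean-center, zero-pad to
# the next power of two >= 2N (linear, not circular, correlation), transform,
# mask the cross-spectrum and invert.
.mcc_core <- function(y, yhat, band) {
  stopifnot(inherits(y, "signal1d"), inherits(yhat, "signal1d"))
  n <- length(y$values)
  if (length(yhat$values) != n)
    stop("mcc: signals must have equal length (", n, " vs ",
         length(yhat$values), ")")
  if (!isTRUE(all.equal(y$fs, yhat$fs)))
    stop("mcc: signals must share a sampling rate")
  yc <- y$values - mean(y$values)
  uc <- yhat$values - mean(yhat$values)
  sy <- sqrt(mean(yc^2))
  su <- sqrt(mean(uc^2))
  if (sy == 0) stop("mcc: ground-truth signal is constant (zero variance)")
  if (su == 0) stop("mcc: predicted signal is constant (zero variance)")
  L <- next_pow2(2L * n)
  Y <- stats::fft(c(yc, rep(0, L - n)))
  U <- stats::fft(c(uc, rep(0, L - n)))
  mask <- bandpass_mask(L, y$fs, band)
  cross <- mask * Y * Conj(U)
  cc_c <- stats::fft(cross, inverse = TRUE) / L
  # power ratio of the ground truth inside the band, over all non-DC power
  py <- Mod(Y)^2
  cpr <- sum(py * mask) / sum(py[-1L])
  list(n = n, L = L, yc = yc, uc = uc, sy = sy, su = su,
       Y = Y, U = U, mask = mask, cc_c = cc_c, cpr = cpr)
}

#' Frequency-domain maximum cross-correlation (MCC)
#'
#' The band-limited, lag-maximized, variance-normalized cross-correlation
#' between a reference signal and a prediction. Both signals are
#' mean-centered, zero-padded to at least twice their length (so the
#' correlation is linear, not circular), transformed, and the band-passed
#' cross-spectrum is inverse-transformed to a cross-correlation over lags.
#' The maximum over all lags is scaled by `cpr`, the fraction of the
#' reference's non-DC power inside the band (a constant with respect to the
#' prediction), and normalized by `N * sigma_y * sigma_yhat` so that a perfect
#' in-band match scores ~1 regardless of length.
#'
#' @param y reference [signal1d] (ground-truth PPG).
#' @param yhat predicted [signal1d]; same length and rate as `y`.
#' @param band passband, default the 40--180 bpm heart-rate band.
#' @return An object of class `mcc_components`: `cross_corr` (correlation by
#'   lag over the padded length), `c_max`, `lag_max` (0-based circular lag),
#'   `sigma_y`, `sigma_yhat` (population SDs of the mean-centered signals),
#'   `cpr`, `mcc`, and `imag_ratio` (numerical Hermitian-symmetry residual).
#' @examples
#' t <- seq(0, 9.97, by = 1/30)
#' y <- signal1d(sin(2 * pi * 1.5 * t), 30)
#' mcc(y, y)$mcc   # ~ 1
#' @export
mcc <- function(y, yhat, band = hr_band()) {
  k <- .mcc_core(y, yhat, band)
  cc <- Re(k$cc_c)
  re_mag <- max(abs(cc))
  imag_ratio <- if (re_mag > 0) max(abs(Im(k$cc_c))) / re_mag else 0
  i_max <- which.max(cc)
  c_max <- cc[i_max]
  val <- k$cpr * c_max / (k$n * k$sy * k$su)
  structure(list(cross_corr = cc, c_max = c_max, lag_max = i_max - 1L,
                 sigma_y = k$sy, sigma_yhat = k$su, cpr = k$cpr,
                 mcc = val, imag_ratio = imag_ratio),
            class = "mcc_components")
}

# Gradient of mcc(y, yhat) with respect to yhat (the argmax lag is treated as
# locally constant). Used by the training loop; checked against finite
# differences in the test suite.
.mcc_grad <- function(y, yhat, band = hr_band()) {
  k <- .mcc_core(y, yhat, band)
  cc <- Re(k$cc_c)
  i_max <- which.max(cc)
  c_max <- cc[i_max]
  kstar <- i_max - 1L
  val <- k$cpr * c_max / (k$n * k$sy * k$su)
  # c(k*) = sum_t ybp((t + k*) mod L) * u_pad(t), ybp = IFFT(mask * Y)
  ybp <- Re(stats::fft(k$mask * k$Y, inverse = TRUE) / k$L)
  idx <- ((seq_len(k$n) - 1L + kstar) %% k$L) + 1L
  dc_du <- ybp[idx]
  g <- k$cpr / (k$n * k$sy) * (dc_du / k$su -
        c_max * k$uc / (k$n * k$su^3))
  g <- g - mean(g)  # chain rule through the mean subtraction
  list(value = val, grad = g)
}

#' Negative Pearson correlation between two signals
#'
#' @param y,yhat equal-length [signal1d] objects with nonzero variance.
#' @return `-cor(y, yhat)`, in `[-1, 1]`.
#' @export
neg_pcc <- function(y, yhat) {
  stopifnot(inherits(y, "signal1d"), inherits(yhat, "signal1d"))
  if (length(y$values) != length(yhat$values))
    stop("neg_pcc: signals must have equal length")
  if (stats::sd(y$values) == 0 || stats::sd(yhat$values) == 0)
    stop("neg_pcc: zero-variance signal")
  -stats::cor(y$values, yhat$values)
}

.neg_pcc_grad <- function(y, yhat) {
  n <- length(y$values)
  yc <- y$values - mean(y$values)
  uc <- yhat$values - mean(yhat$values)
  sy <- sqrt(mean(yc^2)); su <- sqrt(mean(uc^2))
  if (sy == 0 || su == 0) stop("neg_pcc: zero-variance signal")
  r <- mean(yc * uc) / (sy * su)
  g <- -(yc / (n * sy * su) - r * uc / (n * su^2))
  g <- g - mean(g)
  list(value = -r, grad = g)
}

LOSS_KINDS <- c("mse", "negpcc", "mcc", "negmcc")

#' Waveform training losses
#'
#' Scalar losses to minimize between a reference waveform and a prediction:
#' `"mse"` (mean squared error), `"negpcc"` (negative Pearson correlation),
#' `"negmcc"` (negated [mcc], so minimizing it maximizes the band-limited
#' cross-correlation), and `"mcc"` (the raw MCC value, exposed so the
#' sign-flipped ablation can be run).
#'
#' @param kind one of `"mse"`, `"negpcc"`, `"mcc"`, `"negmcc"`.
#' @param y,yhat reference and predicted [signal1d].
#' @param band passband used by the MCC variants.
#' @return A single numeric loss value.
#' @export
loss_value <- function(kind, y, yhat, band = hr_band()) {
  kind <- match.arg(tolower(kind), LOSS_KINDS)
  if (length(y$values) != length(yhat$values))
    stop("loss_value: signals must have equal length")
  switch(kind,
    mse    = mean((y$values - yhat$values)^2),
    negpcc = neg_pcc(y, yhat),
    mcc    = mcc(y, yhat, band)$mcc,
    negmcc = -mcc(y, yhat, band)$mcc)
}

# value + gradient wrt yhat, for the training loop
.loss_grad <- function(kind, y, yhat, band = hr_band()) {
  kind <- match.arg(tolower(kind), LOSS_KINDS)
  switch(kind,
    mse = {
      d <- yhat$values - y$values
      list(value = mean(d^2), grad = 2 * d / length(d))
    },
    negpcc = .neg_pcc_grad(y, yhat),
    mcc = .mcc_grad(y, yhat, band),
    negmcc = {
      g <- .mcc_grad(y, yhat, band)
      list(value = -g$value, grad = -g$grad)
    })
}
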