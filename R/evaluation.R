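#' Band-pass and standardize a waveform for HR evaluation
#'
#' The same preprocessing is applied to predicted and reference waveforms
#' before spectral HR estimation: frequency-bin mask band-pass to the
#' heart-rate band, then standardization to zero mean and unit variance.
#'
#' @param s a [signal1d].
#' @param band passband (default 40--180 bpm).
#' @param window_s the STFT window the signal must support; signals shorter
#'   than one window are rejected.
#' @return A filtered, standardized [signal1d].
#' @export
preprocess_signal <- function(s, band = hr_band(), window_s = 5) {
  stopifnot(inherits(s, "signal1d"))
  n <- length(s$values)
  need <- ceiling(window_s * s$fs)
  if (n < need)
    stop("signal too short for HR evaluation: ", n, " samples < minimum ",
         need, " (one ", window_s, " s window at ", s$fs, " Hz)")
  v <- s$values - mean(s$values)
  L <- next_pow2(n)
  mask <- bandpass_mask(L, s$fs, band)
  V <- stats::fft(c(v, rep(0, L - n)))
  vf <- Re(stats::fft(mask * V, inverse = TRUE) / L)[seq_len(n)]
  sdv <- stats::sd(vf)
  if (sdv == 0)
    stop("signal has no in-band energy after filtering (constant)")
  signal1d((vf - mean(vf)) / sdv, s$fs)
}

#' Sliding-window spectral heart-rate estimate
#'
#' Short-time Fourier analysis: for each window position the heart rate is
#' 60 times the frequency of the magnitude-spectrum maximum restricted to
#' the band. Each Hann-windowed segment is zero-padded to at least 2048
#' samples so the frequency grid is finer than 1 bpm at typical frame rates.
#'
#' @param s a (preprocessed) [signal1d] spanning at least one window.
#' @param window_s window length, seconds (default 5).
#' @param step_s sliding step, seconds (default 0.1).
#' @param band heart-rate passband.
#' @return An `hr_series`: `times` (window centers, s), `hr` (bpm per
#'   window), plus the window parameters.
#' @examples
#' t <- seq(0, 30, by = 1/30)
#' s <- signal1d(sin(2 * pi * 1.2 * t), 30)
#' range(estimate_hr(s)$hr)  # ~72 bpm
#' @export
estimate_hr <- function(s, window_s = 5, step_s = 0.1, band = hr_band()) {
  stopifnot(inherits(s, "signal1d"))
  fs <- s$fs
  win <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  n <- length(s$values)
  if (n < win)
    stop("signal spans ", n, " samples; need >= ", win, " (one window)")
  nwin <- floor((n - win) / step) + 1L
  nfft <- max(2048L, next_pow2(win))
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  in_band <- which(freqs >= band$f_lo & freqs <= band$f_hi)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  hr <- times <- numeric(nwin)
  for (i in seq_len(nwin)) {
    i0 <- (i - 1L) * step
    seg <- s$values[(i0 + 1L):(i0 + win)]
    seg <- (seg - mean(seg)) * hann
    spec <- Mod(stats::fft(c(seg, rep(0, nfft - win))))[in_band]
    hr[i] <- 60 * freqs[in_band[which.max(spec)]]
    times[i] <- (i0 + win / 2) / fs
  }
  structure(list(times = times, hr = hr,
                 window_s = window_s, step_s = step_s),
            class = "hr_series")
}

#' @export
as.data.frame.hr_series <- function(x, ...) {
  data.frame(time_s = x$times, hr_bpm = x$hr)
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series: %d windows (%g s / %g s step), %.1f-%.1f bpm>\n",
              length(x$hr), x$window_s, x$step_s, min(x$hr), max(x$hr)))
  invisible(x)
}

#' HR agreement metrics between two window series
#'
#' @param pred,ref `hr_series` on the same window grid.
#' @return A `metric_report`: `rmse`, `mae` (bpm), `pcc`, and a
#'   `constant_series` flag. When both series are constant the Pearson
#'   correlation is undefined; identical constant series report `pcc = 1`
#'   with the flag set, differing ones report `NA`.
#' @export
compute_metrics <- function(pred, ref) {
  stopifnot(inherits(pred, "hr_series"), inherits(ref, "hr_series"))
  if (length(pred$hr) != length(ref$hr))
    stop("window grids differ in length (", length(pred$hr), " vs ",
         length(ref$hr), ")")
  d <- pred$hr - ref$hr
  rmse <- sqrt(mean(d^2))
  mae <- mean(abs(d))
  constant <- stats::sd(pred$hr) == 0 || stats::sd(ref$hr) == 0
  pcc <- if (!constant) {
    stats::cor(pred$hr, ref$hr)
  } else if (isTRUE(all.equal(pred$hr, ref$hr))) 1 else NA_real_
  structure(list(rmse = rmse, mae = mae, pcc = pcc,
                 constant_series = constant),
            class = "metric_report")
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(rmse = x$rmse, mae = x$mae, pcc = x$pcc,
             constant_series = x$constant_series)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metrics: RMSE %.3f bpm | MAE %.3f bpm | PCC %s%s>\n",
              x$rmse, x$mae,
              ifelse(is.na(x$pcc), "NA", sprintf("%.3f", x$pcc)),
              if (x$constant_series) " (constant series)" else ""))
  invisible(x)
}

#' Multi-run summary statistics with a significance test
#'
#' Summarizes repeated independent training/evaluation runs (mean and
#' standard deviation per metric) and, when a comparator arm is supplied,
#' Welch's two-sided t-test p-value per metric.
#'
#' @param reports list of [compute_metrics] reports (>= 2).
#' @param comparator optional second arm, a list of reports (>= 2).
#' @return A `run_statistics` object: per-metric `mean`, `sd`, `n`, and
#'   `p_value` (NA without a comparator).
#' @export
run_statistics <- function(reports, comparator = NULL) {
  grab <- function(lst, f) vapply(lst, function(r) r[[f]], numeric(1))
  if (length(reports) < 2L)
    stop("need >= 2 runs for a standard deviation")
  metrics <- c("rmse", "mae", "pcc")
  out <- lapply(metrics, function(m) {
    a <- grab(reports, m)
    p <- NA_real_
    if (!is.null(comparator)) {
      if (length(comparator) < 2L)
        stop("comparator arm needs >= 2 runs")
      b <- grab(comparator, m)
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      } else {
        p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
      }
    }
    list(mean = mean(a), sd = stats::sd(a), n = length(a), p_value = p)
  })
  names(out) <- metrics
  structure(out, class = "run_statistics")
}

#' @export
print.run_statistics <- function(x, ...) {
  for (m in names(x))
    cat(sprintf("%-5s mean %.3f  sd %.3f  n %d  p %s\n", m,
                x[[m]]$mean, x[[m]]$sd, x[[m]]$n,
                ifelse(is.na(x[[m]]$p_value), "-",
                       sprintf("%.3g", x[[m]]$p_value))))
  invisible(x)
}

#' End-to-end HR evaluation of a prediction against a reference
#'
#' Convenience wrapper: preprocess both waveforms identically, estimate HR on
#' the shared sliding-window grid, and compute agreement metrics.
#'
#' @param pred,ref [signal1d] waveforms of equal duration and rate.
#' @inheritParams estimate_hr
#' @return A list with `pred_hr`, `ref_hr` (`hr_series`) and `metrics`.
#' @export
evaluate_waveform <- function(pred, ref, window_s = 5, step_s = 0.1,
                              band = hr_band()) {
  hp <- estimate_hr(preprocess_signal(pred, band, window_s),
                    window_s, step_s, band)
  hr <- estimate_hr(preprocess_signal(ref, band, window_s),
                    window_s, step_s, band)
  list(pred_hr = hp, ref_hr = hr, metrics = compute_metrics(hp, hr))
}
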