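# The synthetic pulse-video generator and its recoverability guarantees.

test_that("gen_ppg produces the requested spectral structure", {
  # pure tone: FFT peak at hr_bpm
  p <- ppg_params(hr_bpm = 72, harmonic_ratio = 0, baseline_amp = 0,
                  noise_sd = 0, duration_s = 20)
  s <- gen_ppg(p, seed = 1)
  spec <- Mod(stats::fft(s$values))[1:300]
  f <- (0:299) * 30 / 600
  expect_equal(60 * f[which.max(spec)], 72, tolerance = 0.2)
  # second harmonic at ~0.3 relative amplitude
  p2 <- ppg_params(hr_bpm = 72, harmonic_ratio = 0.3, baseline_amp = 0,
                   noise_sd = 0, duration_s = 20)
  s2 <- gen_ppg(p2, seed = 1)
  spec2 <- Mod(stats::fft(s2$values))[1:300]
  a1 <- max(spec2[abs(f - 1.2) < 0.1])
  a2 <- max(spec2[abs(f - 2.4) < 0.1])
  expect_equal(a2 / a1, 0.3, tolerance = 0.05)
  # determinism and standardization (noise makes the seed matter)
  pn <- ppg_params(hr_bpm = 72, noise_sd = 0.05, duration_s = 20)
  expect_identical(gen_ppg(pn, seed = 7)$values, gen_ppg(pn, seed = 7)$values)
  expect_false(identical(gen_ppg(pn, seed = 7)$values,
                         gen_ppg(pn, seed = 8)$values))
  expect_lt(abs(stats::sd(s2$values) - 1), 1e-9)
  # drift leaving the detection band is rejected
  expect_error(gen_ppg(ppg_params(hr_bpm = 170, hr_drift_bpm_per_s = 5,
                                  duration_s = 10), seed = 1),
               "leaves")
  expect_error(ppg_params(hr_bpm = 30), "45")
})

test_that("rendered clips carry a recoverable pulse in the green channel", {
  fs <- 30
  ppg <- gen_ppg(ppg_params(hr_bpm = 84, duration_s = 10, fs = fs), seed = 5)
  clip <- render_clip(ppg, scene_params(), seed = 6)
  expect_s3_class(clip, "video_clip")
  expect_equal(dim(clip$data), c(3, 300, 32, 32))
  # dominant in-band FFT peak of the masked green trace at the driving HR
  tr <- preprocess_signal(green_trace(clip))
  hr <- estimate_hr(tr)
  expect_lt(max(abs(hr$hr - 84)), 3)
  # null case: without modulation there is no in-band peak at the HR above
  # the noise floor
  sc0 <- scene_params(modulation_rgb = c(0, 0, 0))
  clip0 <- render_clip(ppg, sc0, seed = 6)
  g0 <- green_trace(clip0)
  spec <- Mod(stats::fft(g0$values - mean(g0$values)))[2:150]
  f <- (1:149) * fs / 300
  peak_at_hr <- max(spec[abs(f - 1.4) < 0.1])
  floor_med <- stats::median(spec[f >= 0.667 & f <= 3])
  expect_lt(peak_at_hr, 4 * floor_med)
})

test_that("the handcrafted oracle achieves < 2 bpm RMSE at default noise", {
  fs <- 30
  errs <- c()
  for (i in 1:4) {
    hr_true <- c(55, 75, 100, 140)[i]
    ppg <- gen_ppg(ppg_params(hr_bpm = hr_true, duration_s = 10, fs = fs),
                   seed = 10 + i)
    clip <- render_clip(ppg, scene_params(), seed = 20 + i)
    ev <- evaluate_waveform(green_trace(clip), ppg)
    errs <- c(errs, ev$metrics$rmse)
  }
  expect_lt(sqrt(mean(errs^2)), 2)
})

test_that("difficulty axes behave: noise raises error, motion lowers SNR", {
  fs <- 30
  # noise axis: shrinking the pulse amplitude against fixed sensor noise
  # must not reduce the oracle's HR error (median over 3 seeds)
  med_err <- function(noise_mult) {
    errs <- sapply(1:3, function(sd_i) {
      ppg <- gen_ppg(ppg_params(hr_bpm = 90, duration_s = 8, fs = fs),
                     seed = 30 + sd_i)
      sc <- scene_params(illumination_sd = 0.5 * noise_mult)
      sc$modulation_rgb <- sc$modulation_rgb / noise_mult
      clip <- render_clip(ppg, sc, seed = 40 + sd_i)
      evaluate_waveform(green_trace(clip), ppg)$metrics$rmse
    })
    stats::median(errs)
  }
  expect_lte(med_err(1), med_err(6) + 1e-9)
  # motion axis: the HR error sits on the STFT grid floor at these scales,
  # so the sensitive readout is the in-band SNR of the mean green trace
  med_snr <- function(motion) {
    stats::median(sapply(1:3, function(sd_i) {
      ppg <- gen_ppg(ppg_params(hr_bpm = 90, duration_s = 8, fs = fs),
                     seed = 30 + sd_i)
      clip <- render_clip(ppg, scene_params(motion_amplitude_px = motion),
                          seed = 40 + sd_i)
      g <- green_trace(clip)
      v <- g$values - mean(g$values)
      sp <- Mod(stats::fft(v))^2
      n <- length(v); f <- (0:(n - 1)) * fs / n
      inb <- f >= 40 / 60 & f <= 3
      at_hr <- inb & abs(f - 1.5) < 0.15
      max(sp[at_hr]) / stats::median(sp[inb & !at_hr])
    }))
  }
  expect_gte(med_snr(0), med_snr(3))
})

test_that("8-bit rendering rejects out-of-range amplitudes", {
  ppg <- gen_ppg(ppg_params(duration_s = 2), seed = 1)
  sc <- scene_params(base_rgb = c(250, 250, 250), pixel_depth = "8bit")
  expect_error(render_clip(ppg, sc, seed = 1), "reduce")
  sc_ok <- scene_params(pixel_depth = "8bit")
  clip <- render_clip(ppg, sc_ok, seed = 1)
  expect_true(all(clip$data == round(clip$data)))
})

test_that("make_dataset splits subjects exclusively and reproducibly", {
  ds <- make_dataset(10, duration_s = 16 / 30, seed = 3)
  expect_length(ds$train, 6); expect_length(ds$val, 2); expect_length(ds$test, 2)
  m <- ds$manifest
  subj_by_split <- split(m$subject, m$split)
  expect_length(Reduce(intersect, subj_by_split), 0)
  # same seed -> identical manifest (byte-identical JSON)
  f1 <- tempfile(); f2 <- tempfile()
  save_manifest(make_dataset(10, duration_s = 16 / 30, seed = 3,
                             render = FALSE), f1)
  save_manifest(ds, f2)
  expect_identical(readLines(f1), readLines(f2))
  # labels ride along with their clips
  expect_length(ds$train[[1]]$label$values, 16)
  # grouped subjects stay within one split
  ds2 <- make_dataset(12, clips_per_subject = 3, duration_s = 16 / 30,
                      seed = 4, render = FALSE)
  grp <- split(ds2$manifest$split, ds2$manifest$subject)
  expect_true(all(sapply(grp, function(s) length(unique(s)) == 1)))
})

test_that("sampled heart rates are uniform over the configured range", {
  ds <- make_dataset(200, seed = 9, render = FALSE)
  hrs <- ds$manifest$hr_bpm
  expect_true(all(hrs >= 50 & hrs <= 150))
  cs <- suppressWarnings(
    stats::chisq.test(table(cut(hrs, breaks = seq(50, 150, by = 20)))))
  expect_gt(cs$p.value, 0.01)
})
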