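#' Parameters of a synthetic PPG waveform
#'
#' A pulse waveform model: a fundamental at the heart rate with an optional
#' linear frequency drift, a second harmonic (the dicrotic component of real
#' PPG, default 0.3 relative amplitude), a slow respiratory/baseline-wander
#' term at 0.1 Hz, and additive Gaussian sensor noise. The waveform is
#' standardized to zero mean and unit variance.
#'
#' @param hr_bpm fundamental heart rate, beats per minute (45--170 so the
#'   signal stays inside the 40--180 bpm detection band with margin).
#' @param hr_drift_bpm_per_s linear drift of the instantaneous rate.
#' @param harmonic_ratio second-harmonic amplitude relative to fundamental.
#' @param harmonic_phase phase offset of the second harmonic, radians.
#' @param baseline_freq_hz,baseline_amp slow baseline oscillation.
#' @param noise_sd Gaussian noise SD (pre-standardization units).
#' @param duration_s,fs clip duration (s) and sampling rate (Hz).
#' @return An object of class `ppg_params`.
#' @export
ppg_params <- function(hr_bpm = 72, hr_drift_bpm_per_s = 0,
                       harmonic_ratio = 0.3, harmonic_phase = pi / 4,
                       baseline_freq_hz = 0.1, baseline_amp = 0.1,
                       noise_sd = 0.05, duration_s = 128 / 30, fs = 30) {
  if (hr_bpm < 45 || hr_bpm > 170)
    stop("hr_bpm must lie in [45, 170] (inside the detection band with margin)")
  if (fs < 2 * (2 * hr_bpm / 60))
    stop("fs too low to represent the second harmonic (need fs >= ",
         2 * (2 * hr_bpm / 60), " Hz)")
  structure(as.list(environment()), class = "ppg_params")
}

#' Generate a synthetic PPG waveform
#'
#' @param p a [ppg_params].
#' @param seed RNG seed; the same seed reproduces the signal exactly.
#' @return A standardized [signal1d] of length `round(duration_s * fs)`.
#' @examples
#' s <- gen_ppg(ppg_params(hr_bpm = 66, duration_s = 10), seed = 1)
#' @export
gen_ppg <- function(p, seed = 1L) {
  stopifnot(inherits(p, "ppg_params"))
  n <- round(p$duration_s * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  f_inst <- p$hr_bpm / 60 + p$hr_drift_bpm_per_s * t / 60
  hr_inst <- 60 * f_inst
  if (any(hr_inst < 40 | hr_inst > 180))
    stop("instantaneous heart rate leaves [40, 180] bpm during the clip ",
         "(reached ", round(max(abs(hr_inst)), 1), " bpm); reduce the drift")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  phase <- 2 * pi * cumsum(f_inst) / p$fs
  v <- sin(phase) +
    p$harmonic_ratio * sin(2 * phase + p$harmonic_phase) +
    p$baseline_amp * sin(2 * pi * p$baseline_freq_hz * t) +
    stats::rnorm(n, sd = p$noise_sd)
  signal1d((v - mean(v)) / stats::sd(v), p$fs)
}

#' A video clip with an optional paired PPG label
#'
#' @param data a `(3, T, H, W)` numeric array (channels, frames, rows, cols).
#' @param fs frame rate, Hz.
#' @param label optional ground-truth [signal1d] of length T.
#' @param meta optional list of generation parameters.
#' @return An object of class `video_clip`.
#' @export
video_clip <- function(data, fs, label = NULL, meta = NULL) {
  d <- dim(data)
  if (length(d) != 4L || d[1] != 3L)
    stop("clip data must be a (3, T, H, W) array")
  if (!is.null(label)) {
    stopifnot(inherits(label, "signal1d"))
    if (length(label$values) != d[2])
      stop("label length ", length(label$values),
           " does not match T = ", d[2])
  }
  structure(list(data = data, fs = fs, label = label, meta = meta),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<video_clip: 3 x %d x %d x %d @ %g fps%s>\n",
              d[2], d[3], d[4], x$fs,
              if (!is.null(x$label)) ", labeled" else ""))
  invisible(x)
}

#' Scene parameters for the synthetic pulse video
#'
#' Defines a skin-like elliptic region whose color is modulated by the PPG
#' waveform, over a textured background, with shared illumination
#' fluctuation, per-pixel sensor noise, and small smooth motion of the
#' region. The modulation is green-dominant (R:G:B about 0.5:1:0.4),
#' mimicking hemoglobin absorption ordering; amplitudes are in 8-bit
#' intensity levels and small relative to the base levels, as in real rPPG.
#'
#' @param height,width frame size in pixels.
#' @param center,axes ellipse center (row, col) and semi-axes; defaults to a
#'   centered ellipse covering ~35% of the frame.
#' @param base_rgb baseline skin intensity per channel (0--255 scale).
#' @param modulation_rgb per-channel pulse amplitude (intensity levels).
#' @param texture_sd SD of the static per-pixel skin texture.
#' @param illumination_sd SD of the per-frame shared illumination term.
#' @param motion_amplitude_px bound of the smooth random-walk translation.
#' @param pixel_depth `"continuous"` or `"8bit"` (rounded, range-checked).
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(height = 32L, width = 32L,
                         center = NULL, axes = NULL,
                         base_rgb = c(150, 105, 85),
                         modulation_rgb = c(1.0, 2.0, 0.8),
                         texture_sd = 3, illumination_sd = 0.5,
                         motion_amplitude_px = 0.5,
                         pixel_depth = c("continuous", "8bit")) {
  pixel_depth <- match.arg(pixel_depth)
  if (is.null(center)) center <- c(height / 2, width / 2)
  if (is.null(axes)) axes <- c(0.35 * height, 0.30 * width)
  if (center[1] - axes[1] < 0 || center[1] + axes[1] > height ||
      center[2] - axes[2] < 0 || center[2] + axes[2] > width)
    stop("skin ellipse must lie inside the frame")
  if (any(modulation_rgb > base_rgb / 10))
    stop("modulation amplitudes should be small relative to base levels")
  structure(list(height = as.integer(height), width = as.integer(width),
                 center = center, axes = axes, base_rgb = base_rgb,
                 modulation_rgb = modulation_rgb, texture_sd = texture_sd,
                 illumination_sd = illumination_sd,
                 motion_amplitude_px = motion_amplitude_px,
                 pixel_depth = pixel_depth),
            class = "scene_params")
}

# smooth bounded random walk of length n with max |.| = amp
.smooth_walk <- function(n, amp) {
  if (amp <= 0) return(numeric(n))
  w <- cumsum(stats::rnorm(n))
  k <- max(3L, round(n / 16))
  w <- stats::filter(w, rep(1 / k, k), sides = 2, circular = TRUE)
  w <- as.numeric(w) - mean(w)
  m <- max(abs(w))
  if (m == 0) return(numeric(n))
  w * amp / m
}

#' Render a synthetic pulse video clip
#'
#' Each frame is `base + static texture + modulation * ppg(t)` inside the
#' (possibly translated) skin mask, plus a per-frame shared illumination
#' term and per-pixel Gaussian sensor noise. The mask translation is a
#' smooth bounded random walk.
#'
#' @param ppg the driving waveform ([signal1d]); its length sets T.
#' @param sc a [scene_params].
#' @param seed RNG seed for texture, noise, illumination and motion.
#' @return A [video_clip] carrying `ppg` as its label.
#' @export
render_clip <- function(ppg, sc = scene_params(), seed = 1L) {
  stopifnot(inherits(ppg, "signal1d"), inherits(sc, "scene_params"))
  n_t <- length(ppg$values)
  H <- sc$height; W <- sc$width
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  texture <- matrix(stats::rnorm(H * W, sd = sc$texture_sd), H, W)
  illum <- stats::rnorm(n_t, sd = sc$illumination_sd)
  dy <- .smooth_walk(n_t, sc$motion_amplitude_px)
  dx <- .smooth_walk(n_t, sc$motion_amplitude_px)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  data <- array(0, c(3L, n_t, H, W))
  noise <- array(stats::rnorm(3 * n_t * H * W), c(3L, n_t, H, W))
  for (ti in seq_len(n_t)) {
    mask <- ((rows - sc$center[1] - dy[ti]) / sc$axes[1])^2 +
            ((cols - sc$center[2] - dx[ti]) / sc$axes[2])^2 <= 1
    for (ch in 1:3) {
      fr <- sc$base_rgb[ch] + texture +
        sc$modulation_rgb[ch] * ppg$values[ti] * mask +
        illum[ti] + noise[ch, ti, , ]
      data[ch, ti, , ] <- fr
    }
  }
  if (sc$pixel_depth == "8bit") {
    if (min(data) < 0 || max(data) > 255)
      stop("8-bit rendering out of [0, 255] range (reached [",
           round(min(data), 1), ", ", round(max(data), 1),
           "]); reduce the modulation or noise amplitudes")
    data <- round(data)
  }
  video_clip(data, ppg$fs, label = ppg,
             meta = list(scene = sc, seed = seed))
}

#' Spatial-mean green-channel trace of a clip
#'
#' The classic hand-crafted rPPG extraction: average the green channel over
#' the nominal skin region. Serves as the recoverability oracle for the
#' synthetic data: if this trace's band-limited spectrum peaks at the
#' driving heart rate, the dataset is solvable before any learning.
#'
#' @param clip a [video_clip].
#' @param use_mask restrict to the nominal (untranslated) skin ellipse when
#'   the clip carries scene metadata.
#' @return A [signal1d] at the clip frame rate.
#' @export
green_trace <- function(clip, use_mask = TRUE) {
  stopifnot(inherits(clip, "video_clip"))
  d <- dim(clip$data)
  g <- clip$data[2, , , ]
  dim(g) <- c(d[2], d[3] * d[4])
  if (use_mask && !is.null(clip$meta$scene)) {
    sc <- clip$meta$scene
    rows <- matrix(seq_len(sc$height), sc$height, sc$width)
    cols <- matrix(seq_len(sc$width), sc$height, sc$width, byrow = TRUE)
    mask <- ((rows - sc$center[1]) / sc$axes[1])^2 +
            ((cols - sc$center[2]) / sc$axes[2])^2 <= 1
    g <- g[, as.vector(mask), drop = FALSE]
  }
  signal1d(rowMeans(g), clip$fs)
}

#' Generate a labeled synthetic dataset with subject-exclusive splits
#'
#' Samples heart rates uniformly from `hr_range`, renders one clip per
#' draw, and assigns clips to train/validation/test splits such that
#' "subjects" (a subject is one base color + texture identity, reused
#' across its clips) never straddle splits.
#'
#' @param n_clips total number of clips.
#' @param split named fractions summing to 1 (default 60/20/20).
#' @param hr_range uniform sampling range for the heart rate, bpm.
#' @param duration_s,fs clip duration and frame rate.
#' @param scene base [scene_params]; each subject perturbs `base_rgb`
#'   slightly and owns a texture seed.
#' @param ppg_overrides named list of [ppg_params] fields to override.
#' @param clips_per_subject clips sharing one subject identity.
#' @param seed master seed; all per-clip seeds derive from it.
#' @param render if `FALSE`, return the manifest only (no pixel data) —
#'   useful for inspecting the sampling design cheaply.
#' @return A list with `train`, `val`, `test` (lists of [video_clip]) and
#'   `manifest` (data frame: clip id, subject, split, hr_bpm, seeds).
#' @export
make_dataset <- function(n_clips, split = c(train = 0.6, val = 0.2, test = 0.2),
                         hr_range = c(50, 150), duration_s = 128 / 30, fs = 30,
                         scene = scene_params(), ppg_overrides = list(),
                         clips_per_subject = 1L, seed = 1L, render = TRUE) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_subj <- ceiling(n_clips / clips_per_subject)
  subj_of_clip <- rep(seq_len(n_subj), each = clips_per_subject)[seq_len(n_clips)]
  # allocate subjects to splits so clip counts track the fractions
  counts <- floor(split * n_clips)
  while (sum(counts) < n_clips) {
    i <- which.max(split * n_clips - counts)
    counts[i] <- counts[i] + 1L
  }
  split_of_clip <- character(n_clips)
  pool <- unique(subj_of_clip)
  pos <- 1L
  for (s in names(counts)) {
    need <- counts[[s]]
    got <- 0L
    while (got < need && pos <= length(pool)) {
      sid <- pool[pos]; pos <- pos + 1L
      members <- which(subj_of_clip == sid)
      split_of_clip[members] <- s
      got <- got + length(members)
    }
  }
  hrs <- stats::runif(n_clips, hr_range[1], hr_range[2])
  subj_jitter <- matrix(stats::rnorm(n_subj * 3, sd = 5), n_subj, 3)
  clip_seed <- seed + 1000L + seq_len(n_clips)

  manifest <- data.frame(clip = seq_len(n_clips), subject = subj_of_clip,
                         split = split_of_clip, hr_bpm = hrs,
                         seed = clip_seed, duration_s = duration_s, fs = fs)
  out <- list(train = list(), val = list(), test = list(),
              manifest = manifest, seed = seed)
  if (!render) return(out)
  for (i in seq_len(n_clips)) {
    pp_args <- utils::modifyList(
      list(hr_bpm = hrs[i], duration_s = duration_s, fs = fs), ppg_overrides)
    pp <- do.call(ppg_params, pp_args)
    ppg <- gen_ppg(pp, seed = clip_seed[i])
    sc <- scene
    sc$base_rgb <- scene$base_rgb + subj_jitter[subj_of_clip[i], ]
    cl <- render_clip(ppg, sc, seed = clip_seed[i] + 1L)
    cl$meta$hr_bpm <- hrs[i]
    cl$meta$subject <- subj_of_clip[i]
    out[[split_of_clip[i]]] <- c(out[[split_of_clip[i]]], list(cl))
  }
  out
}

#' Write a dataset manifest as JSON
#'
#' @param dataset a [make_dataset] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
save_manifest <- function(dataset, path) {
  jsonlite::write_json(list(seed = dataset$seed, clips = dataset$manifest),
                       path, dataframe = "rows", digits = 10, auto_unbox = TRUE)
  invisible(path)
}
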