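#' Tile per-channel activation maps into one image
#'
#' Places each channel's 2-D activation map, min-max normalized to [0, 1],
#' into a ceil(sqrt(C))-sided square grid in row-major order; unused cells
#' are zero. A constant (degenerate) channel maps to zeros.
#'
#' @param snapshot a `C x H x W` array (one time point of one layer), or an
#'   `activation_snapshot` from [activation_at].
#' @return A single 2-D matrix of size `(side*H) x (side*W)`.
#' @export
tile_grid <- function(snapshot) {
  x <- if (inherits(snapshot, "activation_snapshot")) snapshot$tensor else snapshot
  d <- dim(x)
  if (length(d) != 3L) stop("expected a C x H x W array")
  C <- d[1]; H <- d[2]; W <- d[3]
  side <- ceiling(sqrt(C))
  out <- matrix(0, side * H, side * W)
  for (k in seq_len(C)) {
    m <- matrix(x[k, , ], H, W)
    rng <- range(m)
    m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    r <- (k - 1L) %/% side
    cc <- (k - 1L) %% side
    out[r * H + seq_len(H), cc * W + seq_len(W)] <- m
  }
  out
}

#' Extract one layer's activation snapshot at a time index
#'
#' Runs the clip through the network recording the full (unpooled) activation
#' of the requested tap, and returns the `C x H_l x W_l` slice at one time
#' index, for [tile_grid].
#'
#' @param network a [build_network] object.
#' @param clip a [video_clip].
#' @param tap_name one of the tap names (`"stem"`, ..., `"decoder2"`).
#' @param t_index time index at the layer's own temporal resolution.
#' @return An `activation_snapshot` (fields `layer_name`, `tensor`).
#' @export
activation_at <- function(network, clip, tap_name, t_index = 1L) {
  stopifnot(inherits(network, "dsenn_network"))
  if (!tap_name %in% names(network$taps)) stop("unknown tap ", tap_name)
  x <- clip$data
  d <- dim(x)
  if (length(d) == 4L) dim(x) <- c(d, 1L)
  pos <- network$taps[[tap_name]]
  for (i in seq_len(pos)) {
    r <- .layer_forward(network$layers[[i]], x, training = FALSE)
    x <- r$out
  }
  dd <- dim(x)
  if (t_index < 1L || t_index > dd[2]) stop("t_index out of range 1..", dd[2])
  tens <- array(x[, t_index, , , 1], c(dd[1], dd[3], dd[4]))
  structure(list(layer_name = tap_name, tensor = tens),
            class = "activation_snapshot")
}

#' Per-channel temporal traces of the intermediate layers
#'
#' One spatially pooled trace per channel per tap, each at that layer's
#' effective sampling rate.
#'
#' @param taps named list of [tap_output] objects (from [forward]).
#' @return A named list (per layer) of lists of [signal1d] (per channel).
#' @export
temporal_traces <- function(taps) {
  lapply(taps, function(tp) {
    lapply(seq_len(nrow(tp$pooled)), function(k)
      signal1d(tp$pooled[k, ], tp$fs_l))
  })
}

#' Magnitude spectra of temporal traces in the heart-rate band
#'
#' DC is removed and the frequency grid is restricted to the band, so a
#' pulse-locked layer shows a dominant peak at the driving heart rate.
#'
#' @param traces one layer's list of [signal1d] traces (an element of
#'   [temporal_traces]), all of equal length >= 8.
#' @param layer_name label carried into the result.
#' @param band passband (default 40--180 bpm).
#' @return A `spectral_trace`: `freq_bpm` grid and a channels x bins
#'   magnitude matrix.
#' @export
spectral_traces <- function(traces, layer_name = "", band = hr_band()) {
  if (inherits(traces, "signal1d")) traces <- list(traces)
  n <- length(traces[[1]]$values)
  if (n < 8L) stop("trace too short for a spectrum (need >= 8 samples)")
  fs <- traces[[1]]$fs
  freqs <- (0:(n %/% 2)) * fs / n
  sel <- which(freqs >= band$f_lo & freqs <= band$f_hi & freqs > 0)
  mag <- t(vapply(traces, function(s) {
    v <- s$values - mean(s$values)
    Mod(stats::fft(v))[sel]
  }, numeric(length(sel))))
  structure(list(layer_name = layer_name, freq_bpm = 60 * freqs[sel],
                 mag = mag),
            class = "spectral_trace")
}

#' Render the learned stem filters as an RGB patch grid
#'
#' Each stem output channel's 3 x 1 x 5 x 5 kernel becomes one 5 x 5 RGB
#' patch (min-max normalized per filter; a constant kernel renders uniform
#' gray and is flagged), tiled row-major into a ceil(sqrt(K)) grid.
#'
#' @param network a [build_network] object (3-channel stem required).
#' @return A `(side*5) x (side*5) x 3` array in [0, 1], with attribute
#'   `degenerate` listing flat filters.
#' @export
filter_grid <- function(network) {
  stopifnot(inherits(network, "dsenn_network"))
  stem <- NULL
  for (l in network$layers) if (l$type == "conv") { stem <- l; break }
  if (stem$cin != 3L)
    stop("stem has ", stem$cin, " input channels; RGB rendering needs 3")
  kh <- stem$kdim[2]; kw <- stem$kdim[3]
  K <- stem$cout
  side <- ceiling(sqrt(K))
  out <- array(0, c(side * kh, side * kw, 3))
  degen <- integer(0)
  for (k in seq_len(K)) {
    wk <- array(stem$w[, k], c(3L, stem$kdim))   # (c, kt, kh, kw)
    patch <- aperm(array(wk[, 1, , ], c(3L, kh, kw)), c(2, 3, 1))
    rng <- range(patch)
    if (diff(rng) > 0) {
      patch <- (patch - rng[1]) / diff(rng)
    } else {
      patch[] <- 0.5
      degen <- c(degen, k)
    }
    r <- (k - 1L) %/% side
    cc <- (k - 1L) %% side
    out[r * kh + seq_len(kh), cc * kw + seq_len(kw), ] <- patch
  }
  attr(out, "degenerate") <- degen
  out
}

#' Write a grayscale matrix or RGB array as PNG
#'
#' @param img matrix (grayscale) or H x W x 3 array, values in [0, 1].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
save_png <- function(img, path) {
  img[!is.finite(img)] <- 0
  img <- pmin(pmax(img, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}
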