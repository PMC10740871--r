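#' Deep-supervision configuration
#'
#' Controls how the primary waveform loss is composed with the spectral
#' auxiliary losses attached to the intermediate-layer taps. The defaults are
#' the proposed training recipe: MSE on the output waveform plus a
#' 0.1-weighted negated-MCC loss on every tap, so that minimizing the
#' auxiliary term maximizes the band-limited cross-correlation between each
#' layer's pooled trace and the (temporally downsampled) PPG label.
#'
#' @param primary_loss loss kind for the output waveform (see [loss_value]).
#' @param aux_loss loss kind for the tap traces.
#' @param aux_weight weight of each tap's auxiliary term relative to the
#'   primary loss (>= 0; 0 disables deep supervision).
#' @param tap_names which taps to supervise; default all six (stem, three
#'   encoder blocks, two decoder layers).
#' @param channel_mode `"mean"` supervises the across-channel mean trace;
#'   `"per_channel"` averages the loss of each channel's trace instead.
#' @return An object of class `supervision_config`.
#' @export
supervision_config <- function(primary_loss = "mse",
                               aux_loss = "negmcc",
                               aux_weight = 0.1,
                               tap_names = names(TAP_T_DIVISORS),
                               channel_mode = c("mean", "per_channel")) {
  primary_loss <- match.arg(tolower(primary_loss), LOSS_KINDS)
  aux_loss <- match.arg(tolower(aux_loss), LOSS_KINDS)
  channel_mode <- match.arg(channel_mode)
  if (aux_weight < 0) stop("aux_weight must be >= 0")
  if (aux_weight > 0 && length(tap_names) == 0)
    stop("tap_names must be nonempty when deep supervision is enabled")
  bad <- setdiff(tap_names, names(TAP_T_DIVISORS))
  if (length(bad)) stop("unknown tap name(s): ", paste(bad, collapse = ", "))
  structure(list(primary_loss = primary_loss, aux_loss = aux_loss,
                 aux_weight = aux_weight, tap_names = tap_names,
                 channel_mode = channel_mode),
            class = "supervision_config")
}

#' Training hyperparameters
#'
#' Defaults follow the standard recipe for this network family: Adam, learning rate 1e-4, weight
#' decay 0.1, batch size 6, 100 epochs.
#'
#' @param epochs number of passes over the training split.
#' @param learning_rate initial Adam learning rate.
#' @param weight_decay L2 coefficient added to the gradient inside Adam.
#' @param batch_size clips per optimization step.
#' @param seed RNG seed for shuffling (weights are seeded at [build_network]).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-4,
                         weight_decay = 0.1, batch_size = 6L, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Downsample a PPG label to a tap's temporal length
#'
#' Linear interpolation on the uniform grid; the sampling rate scales by
#' `target_T / N`, so an in-band spectral peak stays at the same physical
#' frequency.
#'
#' @param ppg a [signal1d].
#' @param target_T desired length, `2 <= target_T <= length(ppg$values)`.
#' @return A [signal1d] of length `target_T` at rate `fs * target_T / N`.
#' @export
downsample_label <- function(ppg, target_T) {
  stopifnot(inherits(ppg, "signal1d"))
  n <- length(ppg$values)
  target_T <- as.integer(target_T)
  if (target_T < 2L) stop("target_T must be >= 2")
  if (target_T > n)
    stop("target_T (", target_T, ") exceeds the label length (", n, ")")
  if (target_T == n) return(ppg)
  v <- stats::approx(seq_len(n), ppg$values,
                     xout = seq(1, n, length.out = target_T))$y
  signal1d(v, ppg$fs * target_T / n)
}

#' Across-channel mean trace of a tap
#'
#' Collapses a tap's channels x time pooled matrix to a single temporal trace
#' by averaging across channels (the decoder channels of a trained network
#' converge to one or two shared temporal patterns, so the mean preserves the
#' consensus signal).
#'
#' @param tap a [tap_output].
#' @return A [signal1d] at the tap's effective rate.
#' @export
tap_trace <- function(tap) {
  stopifnot(inherits(tap, "tap_output"))
  signal1d(colMeans(tap$pooled), tap$fs_l)
}

#' Composite deeply supervised loss
#'
#' `total = primary(rppg, label) + aux_weight * sum over taps of
#' aux(tap trace, label downsampled to the tap length)`. Taps whose trace is
#' degenerate (zero variance, e.g. all-zero activations early in training)
#' are skipped with a warning rather than aborting: a correlation loss has no
#' defined direction there.
#'
#' @param rppg predicted waveform ([signal1d]).
#' @param taps named list of [tap_output] objects.
#' @param label ground-truth PPG ([signal1d], same length as `rppg`).
#' @param sup a [supervision_config].
#' @param band heart-rate passband for the MCC losses.
#' @return A list with `total` and `breakdown` (`primary`, named `aux` terms
#'   already scaled by `aux_weight`, and `skipped` tap names).
#' @export
composite_loss <- function(rppg, taps, label, sup = supervision_config(),
                           band = hr_band()) {
  stopifnot(inherits(sup, "supervision_config"))
  if (length(label$values) != length(rppg$values))
    stop("label length must equal the predicted waveform length")
  primary <- loss_value(sup$primary_loss, label, rppg, band)
  aux <- numeric(0)
  skipped <- character(0)
  if (sup$aux_weight > 0) {
    for (nm in intersect(sup$tap_names, names(taps))) {
      tr <- tap_trace(taps[[nm]])
      lab_ds <- downsample_label(label, length(tr$values))
      if (stats::sd(tr$values) == 0) {
        warning("tap '", nm, "' has a degenerate (constant) trace; skipped")
        skipped <- c(skipped, nm)
        next
      }
      val <- if (sup$channel_mode == "mean") {
        loss_value(sup$aux_loss, lab_ds, tr, band)
      } else {
        p <- taps[[nm]]$pooled
        vals <- apply(p, 1, function(ch) {
          if (stats::sd(ch) == 0) return(NA_real_)
          loss_value(sup$aux_loss, lab_ds, signal1d(ch, taps[[nm]]$fs_l), band)
        })
        mean(vals, na.rm = TRUE)
      }
      aux[nm] <- sup$aux_weight * val
    }
  }
  list(total = primary + sum(aux),
       breakdown = list(primary = primary, aux = aux, skipped = skipped))
}

# ---- optimizer --------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- as.numeric(g) + weight_decay * as.numeric(params[[nm]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# ---- batch loss + gradients (internal) --------------------------------------

# Computes the composite loss and all gradients for one stacked batch.
# xb: (3,T,H,W,N); labels: list of signal1d; returns loss terms, param grads
# and the updated net (BN running stats).
.batch_step <- function(net, xb, labels, sup, band, fs, training = TRUE) {
  N <- dim(xb)[5]
  fwd <- .net_forward(net, xb, training = training, keep_cache = TRUE)
  net <- fwd$net
  T_in <- dim(xb)[2]
  grad_out <- matrix(0, nrow = T_in, ncol = N)
  primary <- 0
  for (n in seq_len(N)) {
    lg <- .loss_grad(sup$primary_loss, labels[[n]],
                     signal1d(fwd$out[, n], fs), band)
    primary <- primary + lg$value / N
    grad_out[, n] <- lg$grad / N
  }
  aux_terms <- numeric(0)
  n_skipped <- 0L
  tap_grads <- list()
  if (sup$aux_weight > 0 && length(sup$tap_names)) {
    for (nm in intersect(sup$tap_names, names(fwd$taps))) {
      p <- fwd$taps[[nm]]                       # (C, T_l, N)
      C <- dim(p)[1]; T_l <- dim(p)[2]
      fs_l <- fs * T_l / T_in
      tg <- array(0, dim(p))
      term <- 0
      for (n in seq_len(N)) {
        tr <- colMeans(matrix(p[, , n], nrow = C))
        if (stats::sd(tr) == 0) { n_skipped <- n_skipped + 1L; next }
        lab_ds <- downsample_label(labels[[n]], T_l)
        lg <- .loss_grad(sup$aux_loss, lab_ds, signal1d(tr, fs_l), band)
        term <- term + sup$aux_weight * lg$value / N
        gch <- sup$aux_weight * lg$grad / (C * N)
        tg[, , n] <- matrix(rep(gch, each = C), nrow = C)
      }
      aux_terms[nm] <- term
      tap_grads[[nm]] <- tg
    }
  }
  grads <- .net_backward(net, fwd, grad_out, tap_grads)
  list(net = net, primary = primary, aux = aux_terms,
       total = primary + sum(aux_terms), grads = grads,
       n_skipped = n_skipped, out = fwd$out)
}

.stack_clips <- function(clips) {
  d <- dim(clips[[1]]$data)
  xb <- array(0, c(d, length(clips)))
  for (i in seq_along(clips)) xb[, , , , i] <- clips[[i]]$data
  xb
}

# ---- training loop ----------------------------------------------------------

#' Train the network with spectral deep supervision
#'
#' Runs the configured optimization loop: shuffled mini-batches, composite
#' loss (primary waveform loss plus 0.1-weighted auxiliary spectral losses on
#' every tap), Adam with weight decay, and per-epoch validation heart-rate
#' RMSE computed with the STFT evaluator. Deterministic given the seeds and
#' single-threaded execution.
#'
#' @param network a [build_network] object.
#' @param dataset a list with `train` and `val` elements, each a list of
#'   [video_clip] objects carrying their `label` PPG (see [make_dataset]).
#' @param sup a [supervision_config].
#' @param tc a [train_config].
#' @param band heart-rate passband.
#' @param window_s STFT window (s) for validation HR; default
#'   `min(5, clip duration)`.
#' @param verbose print one line per epoch.
#' @return A list of class `train_result`: `network` (trained), `history`
#'   (`train_history` data frame: epoch, total/primary/aux losses, val_rmse,
#'   n_skipped_taps).
#' @export
train <- function(network, dataset, sup = supervision_config(),
                  tc = train_config(), band = hr_band(),
                  window_s = NULL, verbose = FALSE) {
  stopifnot(inherits(network, "dsenn_network"),
            inherits(tc, "train_config"))
  clips <- dataset$train
  if (!length(clips)) stop("dataset$train is empty")
  fs <- clips[[1]]$fs
  dur <- dim(clips[[1]]$data)[2] / fs
  if (is.null(window_s)) window_s <- min(5, dur)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(tc$seed)

  params <- .get_params(network)
  state <- .adam_init(params)
  hist <- vector("list", tc$epochs)

  for (ep in seq_len(tc$epochs)) {
    ord <- sample(length(clips))
    ep_total <- ep_primary <- 0; ep_aux <- NULL; n_skip <- 0L; nb <- 0L
    for (b0 in seq(1, length(clips), by = tc$batch_size)) {
      idx <- ord[b0:min(b0 + tc$batch_size - 1L, length(clips))]
      xb <- .stack_clips(clips[idx])
      labels <- lapply(clips[idx], function(cl) cl$label)
      st <- .batch_step(network, xb, labels, sup, band, fs)
      if (!is.finite(st$total))
        stop("non-finite loss at epoch ", ep, ", batch starting ", b0)
      network <- st$net
      upd <- .adam_step(params, st$grads, state,
                        tc$learning_rate, tc$weight_decay)
      params <- upd$params; state <- upd$state
      network <- .set_params(network, params)
      ep_total <- ep_total + st$total
      ep_primary <- ep_primary + st$primary
      if (length(st$aux)) {
        if (is.null(ep_aux)) ep_aux <- st$aux * 0
        ep_aux <- ep_aux + st$aux
      }
      n_skip <- n_skip + st$n_skipped
      nb <- nb + 1L
    }
    val_rmse <- .validate_hr_rmse(network, dataset$val, band, window_s)
    row <- data.frame(epoch = ep, total = ep_total / nb,
                      primary = ep_primary / nb, val_rmse = val_rmse,
                      n_skipped_taps = n_skip)
    if (!is.null(ep_aux))
      for (nm in names(ep_aux)) row[[paste0("aux_", nm)]] <- ep_aux[[nm]] / nb
    hist[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  primary %.5f  val RMSE %.2f bpm",
                      ep, ep_total / nb, ep_primary / nb, val_rmse))
  }
  history <- do.call(rbind, hist)
  class(history) <- c("train_history", class(history))
  structure(list(network = network, history = history,
                 sup = sup, tc = tc, window_s = window_s),
            class = "train_result")
}

.validate_hr_rmse <- function(network, val_clips, band, window_s) {
  if (is.null(val_clips) || !length(val_clips)) return(NA_real_)
  pred_all <- ref_all <- numeric(0)
  for (cl in val_clips) {
    fw <- forward(network, cl)
    p <- fw$rppg
    if (stats::sd(p$values) == 0) return(NA_real_)  # degenerate output
    hp <- estimate_hr(preprocess_signal(p, band, window_s), window_s, 0.1, band)
    hr <- estimate_hr(preprocess_signal(cl$label, band, window_s),
                      window_s, 0.1, band)
    pred_all <- c(pred_all, hp$hr)
    ref_all <- c(ref_all, hr$hr)
  }
  sqrt(mean((pred_all - ref_all)^2))
}

#' Epochs needed to reach a validation HR RMSE threshold
#'
#' @param history a `train_history` (or `train_result`).
#' @param th_bpm threshold in bpm.
#' @return The first epoch whose validation RMSE is below `th_bpm`, or `Inf`
#'   if never reached.
#' @export
epochs_to_threshold <- function(history, th_bpm) {
  if (inherits(history, "train_result")) history <- history$history
  ok <- which(is.finite(history$val_rmse) & history$val_rmse < th_bpm)
  if (length(ok)) ok[1] else Inf
}

#' Write a training history to CSV and a JSON summary
#'
#' @param result a `train_result`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
save_history <- function(result, dir) {
  stopifnot(inherits(result, "train_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "history.csv")
  utils::write.csv(as.data.frame(unclass(result$history)), csv,
                   row.names = FALSE)
  h <- result$history
  summ <- list(epochs = nrow(h),
               final_total = h$total[nrow(h)],
               final_val_rmse = h$val_rmse[nrow(h)],
               best_val_rmse = suppressWarnings(min(h$val_rmse, na.rm = TRUE)),
               epochs_to_10bpm = epochs_to_threshold(h, 10))
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
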