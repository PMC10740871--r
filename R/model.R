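#' Channel-width configuration of the encoder-decoder
#'
#' The architecture hyperparameters swept by the cost-function optimizer: the
#' stem width, the (shared) widths of the three encoder blocks, and the
#' widths of the two decoder layers.
#'
#' Presets: `"baseline"` is the original PhysNet-style encoder-decoder
#' (stem 32, encoder 64/64/64, decoder 64/64; 866,689 trainable parameters at
#' any input size), `"dse"` is the optimized lightweight network (stem and
#' encoders 16, decoders 2/2; 57,087 parameters).
#'
#' @param stem_width stem channel count (>= 1).
#' @param encoder_widths integer vector of length 3.
#' @param decoder_widths integer vector of length 2.
#' @return An object of class `channel_config`.
#' @export
channel_config <- function(stem_width, encoder_widths, decoder_widths) {
  stem_width <- as.integer(stem_width)
  encoder_widths <- as.integer(encoder_widths)
  decoder_widths <- as.integer(decoder_widths)
  if (length(encoder_widths) != 3L) stop("encoder_widths must have length 3")
  if (length(decoder_widths) != 2L) stop("decoder_widths must have length 2")
  if (any(c(stem_width, encoder_widths, decoder_widths) < 1L))
    stop("all channel widths must be >= 1")
  structure(list(stem_width = stem_width,
                 encoder_widths = encoder_widths,
                 decoder_widths = decoder_widths),
            class = "channel_config")
}

#' @rdname channel_config
#' @param name preset name, `"baseline"` or `"dse"`.
#' @export
preset_config <- function(name) {
  switch(match.arg(tolower(name), c("baseline", "dse")),
    baseline = channel_config(32L, c(64L, 64L, 64L), c(64L, 64L)),
    dse      = channel_config(16L, c(16L, 16L, 16L), c(2L, 2L)))
}

# ---- layer constructors (internal) -----------------------------------------

.init_conv <- function(cin, cout, kdim, pad, rng_sd = NULL) {
  ckv <- cin * prod(kdim)
  sd <- if (is.null(rng_sd)) sqrt(2 / ckv) else rng_sd
  list(type = "conv",
       w = matrix(stats::rnorm(ckv * cout, sd = sd), ckv, cout),
       b = numeric(cout),
       cin = cin, cout = cout, kdim = as.integer(kdim), pad = as.integer(pad))
}

.init_tdeconv <- function(cin, cout, kt = 4L, stride = 2L, pad = 1L) {
  sd <- sqrt(2 / (cin * kt))
  list(type = "tdeconv",
       w = matrix(stats::rnorm(cin * kt * cout, sd = sd), cin * kt, cout),
       b = numeric(cout),
       cin = cin, cout = cout, kt = kt, stride = stride, pad = pad)
}

.init_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c),
       momentum = momentum, eps = eps, c = c)
}

.pool_layer <- function(kdim) list(type = "pool", kdim = as.integer(kdim))
.relu_layer <- function() list(type = "relu")
.spool_layer <- function() list(type = "spatial_pool")  # global spatial mean

# The twelve convolutional layers, in order, as named in the field.
NETWORK_LAYER_NAMES <- c("stem-conv1",
                         "encoder1-conv1", "encoder1-conv2",
                         "encoder2-conv1", "encoder2-conv2",
                         "encoder2-conv3", "encoder2-conv4",
                         "encoder3-conv1", "encoder3-conv2",
                         "decoder-conv1", "decoder-conv2",
                         "head-conv1")

#' Build the spatiotemporal encoder-decoder network
#'
#' Constructs the 12-conv-layer PhysNet-style 3D encoder-decoder: a stem
#' (spatial average pooling x2, one (1,5,5) convolution), three encoder
#' blocks of 2, 4 and 2 convolutions with 3x3x3 kernels (the two inner blocks
#' downsample time x2), two temporally strided transposed-convolution decoder
#' layers that restore the input's temporal length, and a 1x1x1 head over the
#' spatially pooled features producing a T-length waveform. Every convolution
#' is followed by batch normalization (affine) and ReLU except the head.
#'
#' Intermediate taps (spatially pooled activations) are exposed at the output
#' of the stem, each encoder block, and each decoder layer.
#'
#' @param config a [channel_config] or preset name.
#' @param input_shape optional `c(3, T, H, W)`; when given it is validated
#'   (T divisible by 4; H and W even, with `H/2 - 8` a positive multiple
#'   of 8 after the stem's pooling and border-trimming convolutions).
#' @param seed integer seed for weight initialization (fan-in-scaled normal).
#' @return An object of class `dsenn_network`.
#' @examples
#' net <- build_network(preset_config("dse"), seed = 1)
#' count_parameters(net)
#' @export
build_network <- function(config, input_shape = NULL, seed = 1L) {
  if (is.character(config)) config <- preset_config(config)
  stopifnot(inherits(config, "channel_config"))
  if (!is.null(input_shape)) .validate_input_shape(input_shape)
  s <- config$stem_width
  e <- config$encoder_widths
  d <- config$decoder_widths
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  conv_block <- function(cin, cout, pad) {
    add(.init_conv(cin, cout, c(3L, 3L, 3L), pad)); add(.init_bn(cout)); add(.relu_layer())
  }

  add(.pool_layer(c(1L, 2L, 2L)))                       # stem spatial pool
  add(.init_conv(3L, s, c(1L, 5L, 5L), c(0L, 0L, 0L)))  # stem-conv1
  add(.init_bn(s)); add(.relu_layer())
  tap_stem <- length(layers)

  conv_block(s,  e[1], c(1L, 0L, 0L))                   # encoder1 (border-trim)
  conv_block(e[1], e[1], c(1L, 0L, 0L))
  add(.pool_layer(c(1L, 2L, 2L)))
  tap_e1 <- length(layers)

  for (i in 1:4) conv_block(if (i == 1) e[1] else e[2], e[2], c(1L, 1L, 1L))
  add(.pool_layer(c(2L, 2L, 2L)))                       # temporal /2
  tap_e2 <- length(layers)

  conv_block(e[2], e[3], c(1L, 1L, 1L))
  conv_block(e[3], e[3], c(1L, 1L, 1L))
  add(.pool_layer(c(2L, 2L, 2L)))                       # temporal /4
  tap_e3 <- length(layers)

  add(.init_tdeconv(e[3], d[1])); add(.init_bn(d[1])); add(.relu_layer())
  tap_d1 <- length(layers)
  add(.init_tdeconv(d[1], d[2])); add(.init_bn(d[2])); add(.relu_layer())
  tap_d2 <- length(layers)

  add(.spool_layer())
  add(.init_conv(d[2], 1L, c(1L, 1L, 1L), c(0L, 0L, 0L)))  # head-conv1

  structure(list(config = config,
                 input_shape = input_shape,
                 layers = layers,
                 layer_names = NETWORK_LAYER_NAMES,
                 n_layers = 12L,
                 taps = c(stem = tap_stem, encoder1 = tap_e1,
                          encoder2 = tap_e2, encoder3 = tap_e3,
                          decoder1 = tap_d1, decoder2 = tap_d2),
                 seed = seed),
            class = "dsenn_network")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Temporal length divisor and schedule of the tap points, relative to input T.
TAP_T_DIVISORS <- c(stem = 1L, encoder1 = 1L, encoder2 = 2L, encoder3 = 4L,
                    decoder1 = 2L, decoder2 = 1L)

.validate_input_shape <- function(shape) {
  if (length(shape) != 4L) stop("input shape must be c(C, T, H, W)")
  c_ <- shape[1]; t_ <- shape[2]; h_ <- shape[3]; w_ <- shape[4]
  if (c_ != 3L) stop("input axis C: expected 3 color channels, got ", c_)
  if (t_ %% 4L != 0L || t_ < 8L)
    stop("input axis T: temporal length ", t_, " must be a multiple of 4 (>= 8)")
  for (ax in list(c("H", h_), c("W", w_))) {
    v <- as.integer(ax[2])
    if (v %% 2L != 0L || (v / 2L - 8L) < 8L || (v / 2L - 8L) %% 8L != 0L)
      stop("input axis ", ax[1], ": spatial size ", v,
           " must be even with (", ax[1], "/2 - 8) a positive multiple of 8",
           " (e.g. 32, 48, 64, 128)")
  }
  invisible(TRUE)
}

#' @export
print.dsenn_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<dsenn_network: stem %d | encoder %s | decoder %s | ",
                     "%d conv layers | %s parameters>\n"),
              cfg$stem_width, paste(cfg$encoder_widths, collapse = "/"),
              paste(cfg$decoder_widths, collapse = "/"),
              x$n_layers, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars: convolution weights and biases plus the
#' affine scale/shift of every batch-normalization layer. Running statistics
#' are buffers, not parameters. The intermediate-layer supervision taps hold
#' no parameters, so the count is independent of whether deep supervision is
#' used.
#'
#' @param x a [channel_config], preset name, or built `dsenn_network`.
#' @return Integer parameter count.
#' @examples
#' count_parameters("baseline")  # 866689
#' count_parameters("dse")       # 57087
#' @export
count_parameters <- function(x) {
  if (is.character(x)) x <- preset_config(x)
  if (inherits(x, "channel_config")) x <- build_network(x, seed = 0L)
  stopifnot(inherits(x, "dsenn_network"))
  tot <- 0L
  for (l in x$layers) {
    tot <- tot + switch(l$type,
      conv = , tdeconv = length(l$w) + length(l$b),
      bn = length(l$gamma) + length(l$beta),
      0L)
  }
  as.integer(tot)
}

# ---- forward / backward engine ---------------------------------------------

# x: (C,T,H,W,N) array. Returns list(out = T x N matrix, taps = list of
# (C_l, T_l, N) arrays keyed by tap name, caches, net (updated BN buffers)).
.net_forward <- function(net, x, training = FALSE, keep_cache = FALSE) {
  d <- dim(x)
  if (length(d) != 5L) stop("expected a (C,T,H,W,N) array")
  .validate_input_shape(d[1:4])
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  taps <- list()
  tap_at <- net$taps
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    r <- .layer_forward(l, x, training)
    if (!is.null(r$layer)) net$layers[[i]] <- r$layer
    if (keep_cache) caches[[i]] <- r$cache
    x <- r$out
    hit <- names(tap_at)[tap_at == i]
    if (length(hit)) taps[[hit]] <- .spatial_pool3(x)
  }
  dx <- dim(x)  # (1, T, 1, 1, N)
  out <- matrix(x, nrow = dx[2], ncol = dx[5])
  list(out = out, taps = taps, caches = caches, net = net)
}

# (C,T,H,W,N) -> (C,T,N) spatial mean
.spatial_pool3 <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4], d[5])
  out <- array(0, c(d[1], d[2], d[5]))
  for (n in seq_len(d[5])) out[, , n] <- rowMeans(m[, , n, drop = FALSE])
  out
}

.layer_forward <- function(l, x, training) {
  d <- dim(x)
  switch(l$type,
    conv = {
      y <- cpp_conv3d_fwd(x, as.integer(d), l$w, l$b, l$kdim, l$pad)
      list(out = y, cache = list(x = x, xdim = d))
    },
    tdeconv = {
      y <- cpp_tdeconv_fwd(x, as.integer(d), l$w, l$b, l$kt, l$stride, l$pad)
      list(out = y, cache = list(x = x, xdim = d))
    },
    pool = {
      if (any(d[2:4] %% l$kdim != 0))
        stop("pooling: dims (T,H,W) = ", paste(d[2:4], collapse = "x"),
             " not divisible by kernel ", paste(l$kdim, collapse = "x"))
      y <- cpp_avgpool3d_fwd(x, as.integer(d), l$kdim)
      list(out = y, cache = list(xdim = d))
    },
    relu = {
      y <- x * (x > 0)
      list(out = y, cache = list(mask = x > 0))
    },
    bn = {
      C <- d[1]; M <- prod(d) / C
      xm <- matrix(x, nrow = C)
      if (training) {
        mu <- rowMeans(xm)
        va <- rowMeans(xm^2) - mu^2
        mom <- l$momentum
        l$run_mean <- (1 - mom) * l$run_mean + mom * mu
        l$run_var  <- (1 - mom) * l$run_var  + mom * va * M / max(1, M - 1)
      } else {
        mu <- l$run_mean; va <- l$run_var
      }
      istd <- 1 / sqrt(va + l$eps)
      xhat <- (xm - mu) * istd
      y <- xhat * l$gamma + l$beta
      dim(y) <- d
      list(out = y, layer = l,
           cache = list(xhat = xhat, istd = istd, d = d, training = training))
    },
    spatial_pool = {
      p <- .spatial_pool3(x)
      y <- array(p, c(d[1], d[2], 1L, 1L, d[5]))
      list(out = y, cache = list(xdim = d))
    },
    stop("unknown layer type ", l$type))
}

# Backward pass. grad_out: T x N matrix (gradient of the scalar loss wrt the
# output waveform); tap_grads: named list of (C_l, T_l, N) arrays injected at
# the tap points (deep supervision). Returns named list of parameter
# gradients ("L<i>.<field>") plus `gx` (gradient wrt the input clip).
.net_backward <- function(net, fwd, grad_out, tap_grads = NULL) {
  caches <- fwd$caches
  if (is.null(caches)) stop("forward pass was run without keep_cache = TRUE")
  nL <- length(net$layers)
  g <- array(grad_out, c(1L, nrow(grad_out), 1L, 1L, ncol(grad_out)))
  grads <- list()
  tap_at <- net$taps
  for (i in rev(seq_len(nL))) {
    hit <- names(tap_at)[tap_at == i]
    if (length(hit) && !is.null(tap_grads[[hit]])) {
      tg <- tap_grads[[hit]]              # (C, T_l, N)
      dg <- dim(g)
      scale <- 1 / (dg[3] * dg[4])
      add <- array(0, dg)
      tg_s <- tg * scale
      for (n in seq_len(dg[5]))
        add[, , , , n] <- rep(tg_s[, , n], times = dg[3] * dg[4])
      g <- g + add
    }
    l <- net$layers[[i]]
    cache <- caches[[i]]
    r <- .layer_backward(l, cache, g)
    g <- r$gx
    if (!is.null(r$pgrads))
      for (nm in names(r$pgrads)) grads[[paste0("L", i, ".", nm)]] <- r$pgrads[[nm]]
  }
  grads$gx <- g
  grads
}

.layer_backward <- function(l, cache, g) {
  switch(l$type,
    conv = {
      r <- cpp_conv3d_bwd(cache$x, as.integer(cache$xdim), l$w, g, l$kdim, l$pad)
      list(gx = r$gx, pgrads = list(w = r$gw, b = r$gb))
    },
    tdeconv = {
      r <- cpp_tdeconv_bwd(cache$x, as.integer(cache$xdim), l$w, g,
                           l$kt, l$stride, l$pad)
      list(gx = r$gx, pgrads = list(w = r$gw, b = r$gb))
    },
    pool = {
      list(gx = cpp_avgpool3d_bwd(g, as.integer(cache$xdim), l$kdim))
    },
    relu = {
      list(gx = g * cache$mask)
    },
    bn = {
      d <- cache$d
      C <- d[1]; M <- prod(d) / C
      gm <- matrix(g, nrow = C)
      xhat <- cache$xhat
      dgamma <- rowSums(gm * xhat)
      dbeta <- rowSums(gm)
      if (cache$training) {
        gx <- (l$gamma * cache$istd / M) *
          (M * gm - xhat * dgamma - dbeta)
      } else {
        gx <- gm * (l$gamma * cache$istd)
      }
      dim(gx) <- d
      list(gx = gx, pgrads = list(gamma = dgamma, beta = dbeta))
    },
    spatial_pool = {
      d <- cache$xdim
      gx <- array(0, d)
      gsc <- g / (d[3] * d[4])   # (C,T,1,1,N)
      for (n in seq_len(d[5]))
        gx[, , , , n] <- rep(gsc[, , 1, 1, n], times = d[3] * d[4])
      list(gx = gx)
    },
    stop("unknown layer type"))
}

# flat named parameter access for the optimizer
.get_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    flds <- switch(l$type, conv = , tdeconv = c("w", "b"),
                   bn = c("gamma", "beta"), NULL)
    for (f in flds) out[[paste0("L", i, ".", f)]] <- l[[f]]
  }
  out
}

.set_params <- function(net, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- as.integer(sub("^L", "", parts[1]))
    f <- parts[2]
    val <- params[[nm]]
    old <- net$layers[[i]][[f]]
    if (is.matrix(old)) dim(val) <- dim(old)
    net$layers[[i]][[f]] <- val
    }
  net
}

#' Run a clip through the network
#'
#' Evaluation-mode forward pass for a single clip, returning the predicted
#' rPPG waveform and the spatially pooled intermediate-layer taps.
#'
#' @param network a [build_network] object.
#' @param clip a [video_clip] (or bare `(3,T,H,W)` array with `fs` supplied).
#' @param fs frame rate in Hz; taken from the clip when it is a `video_clip`.
#' @return A list with `rppg` (a [signal1d] of length T at the clip frame
#'   rate) and `taps`, a list of `tap_output` objects (fields `layer_name`,
#'   `pooled` C x T_l matrix, `fs_l`).
#' @export
forward <- function(network, clip, fs = NULL) {
  stopifnot(inherits(network, "dsenn_network"))
  if (inherits(clip, "video_clip")) {
    fs <- clip$fs
    x <- clip$data
  } else {
    x <- clip
    if (is.null(fs)) stop("fs must be supplied for a bare array clip")
  }
  d <- dim(x)
  if (length(d) == 4L) dim(x) <- c(d, 1L)
  r <- .net_forward(network, x, training = FALSE, keep_cache = FALSE)
  T_in <- dim(x)[2]
  taps <- lapply(names(r$taps), function(nm) {
    p <- r$taps[[nm]]
    tap_output(nm, matrix(p[, , 1], nrow = dim(p)[1]),
               fs_l = fs * dim(p)[2] / T_in)
  })
  names(taps) <- names(r$taps)
  list(rppg = signal1d(r$out[, 1], fs), taps = taps)
}

#' Spatially pooled intermediate-layer activation
#'
#' @param layer_name tap name (`"stem"`, `"encoder1"`, ..., `"decoder2"`).
#' @param pooled channels x time matrix (spatial mean already applied).
#' @param fs_l effective sampling rate at that depth, Hz.
#' @return An object of class `tap_output`.
#' @export
tap_output <- function(layer_name, pooled, fs_l) {
  stopifnot(is.matrix(pooled), fs_l > 0)
  structure(list(layer_name = layer_name, pooled = pooled, fs_l = fs_l),
            class = "tap_output")
}
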