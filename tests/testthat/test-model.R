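# Architecture reconstruction: the reference parameter anchors, shape
# contracts, and backprop correctness of the hand-built 3D CNN.

test_that("parameter counts reproduce the three reference anchors", {
  # baseline PhysNet encoder-decoder: reference value 866.69 k
  expect_lte(abs(count_parameters("baseline") - 866690), 5)
  # proposed lightweight configuration: reference value 57.09 k
  expect_lte(abs(count_parameters("dse") - 57090), 5)
  # encoder width 16 with the decoder untouched: "from 867 k to 78 k"
  enc16 <- channel_config(16, c(16, 16, 16), c(64, 64))
  expect_equal(round(count_parameters(enc16) / 1000), 78)
  # the stated 91% reduction
  expect_equal(round(100 * (1 - count_parameters(enc16) /
                              count_parameters("baseline"))), 91)
})

test_that("parameter count grows strictly with every width", {
  base <- channel_config(8, c(8, 8, 8), c(4, 4))
  p0 <- count_parameters(base)
  expect_gt(count_parameters(channel_config(16, c(8, 8, 8), c(4, 4))), p0)
  expect_gt(count_parameters(channel_config(8, c(16, 16, 16), c(4, 4))), p0)
  expect_gt(count_parameters(channel_config(8, c(8, 8, 8), c(8, 8))), p0)
  # doubling everything
  expect_gt(count_parameters(channel_config(16, c(16, 16, 16), c(8, 8))), p0)
})

test_that("network has 12 named conv layers and taps hold no parameters", {
  net <- build_network("dse")
  expect_equal(net$n_layers, 12L)
  expect_equal(net$layer_names[1], "stem-conv1")
  expect_equal(net$layer_names[7], "encoder2-conv4")
  expect_equal(net$layer_names[11], "decoder-conv2")
  n_conv <- sum(vapply(net$layers, function(l)
    l$type %in% c("conv", "tdeconv"), logical(1)))
  expect_equal(n_conv, 12L)
  expect_length(net$taps, 6L)
})

test_that("minimal-width network builds and emits a finite waveform", {
  net <- build_network(channel_config(1, c(1, 1, 1), c(1, 1)), seed = 2)
  x <- array(rnorm(3 * 8 * 32 * 32), c(3, 8, 32, 32))
  fw <- forward(net, x, fs = 30)
  expect_length(fw$rppg$values, 8)
  expect_true(all(is.finite(fw$rppg$values)))
})

test_that("forward output length equals input T and taps follow the schedule", {
  net <- build_network("dse", seed = 4)
  for (Tn in c(16L, 64L)) {
    x <- array(rnorm(3 * Tn * 32 * 32, sd = 0.3), c(3, Tn, 32, 32))
    fw <- forward(net, x, fs = 30)
    expect_length(fw$rppg$values, Tn)
    sched <- c(stem = 1L, encoder1 = 1L, encoder2 = 2L, encoder3 = 4L,
               decoder1 = 2L, decoder2 = 1L)
    for (nm in names(sched)) {
      tp <- fw$taps[[nm]]
      expect_equal(ncol(tp$pooled), Tn / sched[[nm]], info = nm)
      expect_equal(tp$fs_l, 30 / sched[[nm]], info = nm)
    }
  }
})

test_that("evaluation-mode forward is deterministic (bitwise)", {
  net <- build_network("dse", seed = 8)
  set.seed(99)
  x <- array(rnorm(3 * 16 * 32 * 32), c(3, 16, 32, 32))
  a <- forward(net, x, fs = 30)
  b <- forward(net, x, fs = 30)
  expect_identical(a$rppg$values, b$rppg$values)
  expect_identical(a$taps$decoder2$pooled, b$taps$decoder2$pooled)
})

test_that("zero clip through a zeroed head yields exactly the head bias", {
  net <- build_network(channel_config(2, c(2, 2, 2), c(2, 2)), seed = 3)
  ih <- length(net$layers)              # head conv is the last layer
  net$layers[[ih]]$w[] <- 0
  net$layers[[ih]]$b[] <- 0.37
  x <- array(0, c(3, 8, 32, 32))
  fw <- forward(net, x, fs = 30)
  expect_equal(fw$rppg$values, rep(0.37, 8), tolerance = 1e-12)
})

test_that("indivisible input shapes fail with the offending axis named", {
  net <- build_network("dse")
  expect_error(forward(net, array(0, c(3, 10, 32, 32)), fs = 30), "axis T")
  expect_error(forward(net, array(0, c(3, 16, 20, 32)), fs = 30), "axis H")
  expect_error(forward(net, array(0, c(3, 16, 32, 31)), fs = 30), "axis W")
  expect_error(forward(net, array(0, c(4, 16, 32, 32)), fs = 30), "axis C")
})

test_that("weight initialization is reproducible and seed-sensitive", {
  a <- build_network("dse", seed = 5)
  b <- build_network("dse", seed = 5)
  c_ <- build_network("dse", seed = 6)
  expect_identical(dsenn:::.get_params(a), dsenn:::.get_params(b))
  expect_false(identical(dsenn:::.get_params(a), dsenn:::.get_params(c_)))
})

test_that("backprop matches finite differences through the whole network", {
  set.seed(21)
  net <- build_network(channel_config(2, c(2, 2, 2), c(2, 2)), seed = 13)
  Tn <- 8; fs <- 30; N <- 2
  xb <- array(rnorm(3 * Tn * 32 * 32 * N, sd = 0.5), c(3, Tn, 32, 32, N))
  labels <- lapply(1:N, function(i) signal1d(rnorm(Tn), fs))
  sup <- supervision_config()          # MSE + 0.1 * negMCC on all taps
  band <- hr_band()
  bs <- dsenn:::.batch_step(net, xb, labels, sup, band, fs)
  loss_at <- function(params) {
    dsenn:::.batch_step(dsenn:::.set_params(net, params),
                        xb, labels, sup, band, fs)$total
  }
  params <- dsenn:::.get_params(net)
  eps <- 1e-5
  checked <- 0L
  for (nm in names(params)) {
    i <- sample(length(params[[nm]]), 1)
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    an <- as.numeric(bs$grads[[nm]])[i]
    # conv biases feeding batch-norm have a true gradient of exactly 0;
    # compare against FD noise there with an absolute tolerance
    expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 1e-3)
    checked <- checked + 1L
  }
  expect_gte(checked, 20L)  # every parameter tensor was probed
})
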