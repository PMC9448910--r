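lif0 <- function() list(Cm = 1, gl = 0, Vth = 1)

test_that("spike tensors validate shapes and expose counts and trains", {
  g <- sim_grid(0.01, 1)
  S <- matrix(0, g$n_steps, 4)
  S[c(10, 20, 30), 2] <- 1
  x <- spike_tensor(S, 4, g)
  expect_equal(tensor_counts(x), c(0, 3, 0, 0))
  expect_equal(tensor_frequencies(x), c(0, 3, 0, 0))
  expect_equal(n_spikes(tensor_train(x, 2)), 3)
  expect_error(spike_tensor(S, c(2, 3), g), "shape error")
})

test_that("the spiking dense layer integrates weighted trains per output unit", {
  g <- sim_grid(0.01, 2)
  code <- rate_code(10, g)
  input <- encode_tensor(c(1, 0.5), code)

  # zero weights: silent
  spec0 <- layer_dense(matrix(0, 3, 2)); spec0$lif <- lif0()
  expect_equal(tensor_counts(snn_dense(input, spec0)), c(0, 0, 0))

  # unit weight, unit threshold, no leak: every input spike fires
  spec1 <- layer_dense(matrix(c(1, 0), 1, 2)); spec1$lif <- lif0()
  expect_equal(tensor_counts(snn_dense(input, spec1)), 20)

  expect_error(snn_dense(input, {
    s <- layer_dense(matrix(1, 2, 3)); s$lif <- lif0(); s
  }), "shape error")
  expect_error(snn_dense(input, layer_dense(matrix(1, 1, 2))),
               "LIF parameters")
})

test_that("a mapped bias-free dense layer reproduces its ReLU reference within the coding bound", {
  g <- sim_grid(0.01, 3)
  code <- rate_code(10, g)
  for (seed in 1:20) {
    set.seed(seed)
    W <- matrix(rnorm(4 * 8), 4, 8)
    W <- W * 0.8 / rowSums(abs(W))
    x <- runif(8)
    spec <- layer_dense(W)
    spec$lif <- lif0()
    f_out <- tensor_frequencies(snn_dense(encode_tensor(x, code), spec))
    f_ann <- ann_forward(x * 10, spec)
    expect_true(all(abs(f_out - f_ann) <= 2 / g$t_window + 1e-9))
  }
})

test_that("spiking convolution superposes receptive fields exactly before threshold", {
  g <- sim_grid(0.01, 2)
  code <- rate_code(10, g)
  set.seed(9)
  img <- array(runif(5 * 5), dim = c(5, 5, 1))
  input <- encode_tensor(img, code)

  # zero filter: silent map
  k0 <- layer_conv2d(array(0, c(3, 3, 1, 1))); k0$lif <- lif0()
  expect_true(all(tensor_counts(snn_conv2d(input, k0)) == 0))

  # 1x1 unit filter: pass-through of spike counts at same shape
  k1 <- layer_conv2d(array(1, c(1, 1, 1, 1))); k1$lif <- lif0()
  out1 <- snn_conv2d(input, k1)
  expect_equal(out1$shape, c(5L, 5L, 1L))
  expect_equal(tensor_counts(out1), tensor_counts(input))

  # pre-threshold linearity: the summed input amplitude at each location
  # equals the plain nested-loop cross-correlation of the filter with the
  # per-pixel spike-count map (zero padding, no kernel flip)
  kern <- matrix(rnorm(9), 3, 3)
  spec <- layer_conv2d(array(kern, c(3, 3, 1, 1)), padding = "same")
  cw <- lifmap:::conv_weight_matrix(spec, c(5L, 5L, 1L))
  counts <- matrix(colSums(input$steps), 5, 5)
  charge_tot <- as.numeric(cw$W %*% as.numeric(counts))
  expect_equal(matrix(charge_tot, 5, 5), naive_xcorr(counts, kern, 1),
               tolerance = 1e-12)

  # channel mismatch is a shape error
  k2 <- layer_conv2d(array(1, c(3, 3, 2, 1))); k2$lif <- lif0()
  expect_error(snn_conv2d(input, k2), "channels")
})

test_that("a mapped 3x3 averaging convolution matches the ReLU conv at the centre pixel", {
  g <- sim_grid(0.01, 3)
  code <- rate_code(10, g)
  img <- array(0.5, dim = c(5, 5, 1))     # uniform 5 Hz input patch
  spec <- layer_conv2d(array(1, c(3, 3, 1, 1)), padding = "same")
  spec$lif <- lif0()
  out <- snn_conv2d(encode_tensor(img, code), spec)
  centre <- 3 + 2 * 5                      # (3, 3) column-major
  f_centre <- tensor_frequencies(out)[centre]
  expect_equal(f_centre, 9 * 1 * 5, tolerance = 2 / g$t_window)
  expect_equal(as.numeric(ann_forward(img * 10, spec))[centre], 45)
})

test_that("spiking max-pooling forwards the busiest train unchanged with a first-member tie-break", {
  g <- sim_grid(0.01, 1)
  S <- matrix(0, g$n_steps, 4)             # one 2x2 window, counts 3,1,2,0
  S[c(5, 15, 25), 1] <- 1
  S[10, 2] <- 1
  S[c(40, 60), 3] <- 1
  x <- spike_tensor(S, c(2, 2, 1), g)
  pooled <- snn_maxpool2d(x, layer_maxpool2d(c(2, 2)))
  expect_equal(pooled$shape, c(1L, 1L, 1L))
  expect_equal(pooled$steps[, 1], S[, 1])  # timing preserved, only selected

  # all counts equal: the first window member (h fastest, then w) wins
  Se <- matrix(0, g$n_steps, 4)
  Se[5, 1] <- 1; Se[10, 2] <- 1; Se[15, 3] <- 1; Se[20, 4] <- 1
  xe <- spike_tensor(Se, c(2, 2, 1), g)
  pe <- snn_maxpool2d(xe, layer_maxpool2d(c(2, 2)))
  expect_equal(pe$steps[, 1], Se[, 1])

  # pooled count map equals the artificial max-pool of the count map
  set.seed(21)
  Sr <- matrix(rbinom(g$n_steps * 16, 1, 0.05), g$n_steps, 16)
  xr <- spike_tensor(Sr, c(4, 4, 1), g)
  pr <- snn_maxpool2d(xr, layer_maxpool2d(c(2, 2)))
  ann_pool <- ann_forward(array(colSums(Sr), c(4, 4, 1)),
                          layer_maxpool2d(c(2, 2)))
  expect_equal(tensor_counts(pr), as.numeric(ann_pool))
})

test_that("the artificial forward pass computes dense, conv, pool and flatten layers", {
  # printed two-input parameters: 0.3*10 + 0.2*10 - 2.16 = 2.84
  d <- layer_dense(matrix(c(0.3, 0.2), 1, 2), bias = -2.16, slope = 1)
  expect_equal(ann_forward(c(10, 10), d), 2.84)
  # rectification
  expect_equal(ann_forward(c(1, 1), d), 0)

  expect_equal(as.numeric(ann_forward(array(runif(16), c(4, 4, 1)),
                                      layer_conv2d(array(0, c(3, 3, 1, 2))))),
               rep(0, 32))
  expect_equal(as.numeric(ann_forward(array(c(3, 1, 2, 0), c(2, 2, 1)),
                                      layer_maxpool2d(c(2, 2)))), 3)

  # flatten contract: column-major (H fastest, then W, then C)
  a <- array(1:12, dim = c(2, 3, 2))
  expect_equal(ann_forward(a, layer_flatten()), as.numeric(1:12))
})
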