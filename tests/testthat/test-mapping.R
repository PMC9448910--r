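test_that("slope maps to 1/(Vth*Cm) and bias-free neurons map to zero leak", {
  m1 <- relu_to_lif(relu_params(c(0.3, 0.2), bias = 0, slope = 1),
                    mapping_config(v_th = 1))
  expect_equal(m1$params$Cm, 1)
  expect_equal(m1$params$gl, 0)
  expect_identical(m1$params$reset_mode, "linear")
  expect_equal(m1$weights, c(0.3, 0.2))

  m2 <- relu_to_lif(relu_params(0.5, bias = 0, slope = 2),
                    mapping_config(v_th = 1))
  expect_equal(m2$params$Cm, 0.5)

  expect_error(relu_to_lif(relu_params(0.5, bias = 0.3)), "bias <= 0")
  expect_error(relu_to_lif(relu_params(c(0.7, 0.5), bias = -1)),
               "mapping-domain")
  expect_error(relu_to_lif(relu_params(c(-0.2, 0.1), bias = -1)),
               "mapping-domain")
})

test_that("the printed bias -2.16 and leak conductance 3 are two sides of one neuron", {
  # with weights (0.3, 0.2), Cm = Vth = 1 the zero-crossing-consistent
  # bias of gl = 3 is 0.5 * 3 / log(0.5) = -2.1640...
  w <- c(0.3, 0.2)
  r <- lif_to_relu(lif_params(Cm = 1, gl = 3, Vth = 1), w)
  expect_equal(r$bias, -2.16, tolerance = 0.005)
  expect_equal(r$bias, 1.5 / log(0.5), tolerance = 1e-12)
  expect_equal(r$slope, 1)
  # the zero-crossing frequency equals the asymptotic minimum firing
  # frequency
  expect_equal(-r$bias / sum(w),
               min_firing_frequency(lif_params(Cm = 1, gl = 3, Vth = 1),
                                    w, t_window = 1e6),
               tolerance = 1e-9)
  # the alternative printed-table variant is exposed for comparison
  expect_equal(attr(r, "bias_printed"), -1.5 * log(0.5), tolerance = 1e-12)

  # and the inverse map recovers gl = 3 from the printed bias
  m <- relu_to_lif(relu_params(w, bias = 1.5 / log(0.5), slope = 1),
                   mapping_config(v_th = 1))
  expect_equal(m$params$gl, 3, tolerance = 1e-9)
})

test_that("relu_to_lif and lif_to_relu are mutually inverse", {
  set.seed(5)
  for (i in 1:30) {
    k <- runif(1, 0.5, 3)
    v_th <- runif(1, 0.5, 2)
    Cm <- 1 / (k * v_th)
    w <- runif(3, 0.02, 0.3) * v_th * Cm   # sum(w) < Vth*Cm
    b <- -runif(1, 0, 2)
    relu <- relu_params(w, bias = b, slope = k)
    m <- relu_to_lif(relu, mapping_config(v_th = v_th))
    back <- lif_to_relu(m$params, m$weights, mapping_config(v_th = v_th))
    expect_equal(back$weights, w, tolerance = 1e-9)
    expect_equal(back$bias, b, tolerance = 1e-9)
    expect_equal(back$slope, k, tolerance = 1e-9)
    # bias = 0 <=> gl = 0 and larger |bias| => larger gl
    expect_gte(m$params$gl, 0)
    if (b == 0) expect_equal(m$params$gl, 0)
  }
  # monotone: larger |bias| gives larger leak
  gls <- vapply(c(-0.5, -1, -2), function(b)
    relu_to_lif(relu_params(c(0.3, 0.2), bias = b))$params$gl, 0)
  expect_false(is.unsorted(gls))
})

test_that("minimum firing frequency: leak-free count law, divergence, and gl monotonicity", {
  # leak-free: the first spike needs Vth*Cm/sum(w) = 2 inputs in 4 s
  p0 <- lif_params(Cm = 1, gl = 0, Vth = 1)
  expect_equal(min_firing_frequency(p0, c(0.3, 0.2), 4), 0.5)

  # the minimum frequency falls as the combined weight approaches the
  # threshold charge (threshold easier and easier to reach) and diverges
  # as the weight vanishes; beyond the log-domain boundary the formula is
  # undefined
  f_near <- vapply(c(0.9, 0.99, 0.999), function(s)
    min_firing_frequency(lif_params(Cm = 1, gl = 1, Vth = 1),
                         s, t_window = 1e9), 0)
  expect_true(all(diff(f_near) < 0))
  f_small <- vapply(c(0.1, 0.01, 0.001), function(s)
    min_firing_frequency(lif_params(Cm = 1, gl = 1, Vth = 1),
                         s, t_window = 1e9), 0)
  expect_true(all(diff(f_small) > 0))
  expect_gt(f_small[3], 100)
  expect_error(min_firing_frequency(lif_params(Cm = 1, gl = 1, Vth = 1),
                                    1.2, 1e9), "mapping-domain")

  # strictly increasing in gl
  fs <- vapply(seq(0.5, 4, by = 0.5), function(g)
    min_firing_frequency(lif_params(Cm = 1, gl = g, Vth = 1),
                         c(0.3, 0.2), 4), 0)
  expect_true(all(diff(fs) > 0))

  # the gl -> 0 limit joins the leak-free branch continuously
  expect_equal(min_firing_frequency(lif_params(Cm = 1, gl = 1e-9, Vth = 1),
                                    c(0.3, 0.2), 4),
               0.5, tolerance = 1e-6)
})

test_that("analytic minimum firing frequency matches the simulate-based bisection", {
  g <- sim_grid(0.01, 3)
  set.seed(101)
  for (i in 1:25) {
    Cm <- runif(1, 0.5, 2)
    gl <- runif(1, 0.2, 3)
    w <- runif(2, 0.05, 0.35) * Cm
    p <- lif_params(Cm = Cm, gl = gl, Vth = 1)
    fa <- min_firing_frequency(p, w, g$t_window)
    fs <- min_firing_frequency_sim(p, w, g)
    expect_lte(abs(fa - fs), 1 / g$t_window)
  }
})

test_that("predicted output frequency: exact staircase and proportional law", {
  p0 <- lif_params(Cm = 1, gl = 0, Vth = 1)
  r1 <- predicted_output_frequency(10, 1, p0, 3)
  expect_equal(r1$n_star, 1L)
  expect_equal(r1$exact, 10)
  expect_equal(r1$approx, 10)

  r2 <- predicted_output_frequency(10, 0.5, p0, 3)
  expect_equal(r2$n_star, 2L)
  expect_equal(r2$exact, 5)

  # with leak, the exact staircase is the reset-to-zero rate: the
  # surplus-discarding neuron restarts from zero after each spike, so it
  # fires exactly once per n_star inputs; the linear reset can only do
  # better
  g <- sim_grid(0.01, 3)
  p3z <- lif_params(Cm = 1, gl = 3, Vth = 1, reset_mode = "zero")
  p3l <- lif_params(Cm = 1, gl = 3, Vth = 1, reset_mode = "linear")
  w <- c(0.3, 0.2)
  pred <- predicted_output_frequency(c(20, 20), w, p3l, 3)
  tr_in <- periodic_train(20, sum(w), g)
  f_zero <- sum(lif_simulate(tr_in, p3z, g)$S) / 3
  f_lin <- sum(lif_simulate(tr_in, p3l, g)$S) / 3
  expect_lte(abs(pred$exact - f_zero), 1 / 3)
  expect_gte(f_lin, pred$exact)

  # unequal input frequencies: only the proportional law applies
  r4 <- predicted_output_frequency(c(10, 20), c(0.3, 0.2), p0, 3)
  expect_true(is.na(r4$exact))
  expect_equal(r4$approx, 7)
})

test_that("mapping reports serialise to JSON with both bias variants", {
  path <- tempfile(fileext = ".json")
  mapping_report(relu_params(c(0.3, 0.2), bias = 1.5 / log(0.5)),
                 mapping_config(v_th = 1, t_window = 4), path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$lif$gl, 3, tolerance = 1e-9)
  expect_true(got$valid_bias_domain)
  expect_equal(got$f_min_zero_crossing, -(1.5 / log(0.5)) / 0.5,
               tolerance = 1e-9)
  expect_equal(got$round_trip_bias, 1.5 / log(0.5), tolerance = 1e-9)
  expect_gt(got$bias_printed, 0)
})
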