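test_that("closed-form potential matches leak-free arithmetic and the fine-grid oracle", {
  p0 <- lif_params(Cm = 1, gl = 0, Vth = 1)
  expect_equal(closed_form_potential(p0, 0.5, 0.2, 1), 0.5)
  expect_equal(closed_form_potential(p0, 0.5, 0.05, 4), 2.0)

  # frozen value from a dt = 1e-5 forward-Euler integration of three
  # impulses of amplitude 0.5 at 0.1 s spacing with gl = 3
  p3 <- lif_params(Cm = 1, gl = 3, Vth = 1)
  expect_equal(closed_form_potential(p3, 0.5, 0.1, 3), 1.1448149284,
               tolerance = 1e-6)

  # vanishing leak recovers the leak-free count
  p_eps <- lif_params(Cm = 1, gl = 1e-12, Vth = 1)
  expect_equal(closed_form_potential(p_eps, 0.5, 0.1, 4), 2.0,
               tolerance = 1e-9)

  expect_error(closed_form_potential(p0, 0.5, -0.1, 1), "period")
  expect_error(closed_form_potential(p0, 0.5, 0.1, 0), "positive integer")
  expect_error(lif_params(Cm = -1), "Cm")
  expect_error(lif_params(gl = -2), "gl")
})

test_that("simulation handles empty, single-spike and periodic inputs exactly", {
  g <- sim_grid(0.01, 1)

  # empty input: silent, potential identically zero
  tr <- lif_simulate(spike_train(numeric(0), grid = g),
                     lif_params(Cm = 1, gl = 2, Vth = 1), g)
  expect_equal(sum(tr$S), 0)
  expect_true(all(tr$V == 0) && all(tr$H == 0))

  # a single event of amplitude Vth*Cm fires once and resets to 0 in
  # both modes
  for (mode in c("linear", "zero")) {
    p <- lif_params(Cm = 2, gl = 1, Vth = 0.5, reset_mode = mode)
    tr <- lif_simulate(spike_train(0.5, 0.5 * 2, g), p, g)
    expect_equal(sum(tr$S), 1)
    expect_equal(tr$S[50], 1L)
    expect_equal(tr$V[50], 0)
  }

  # ten events of amplitude 0.5 at 10 Hz, leak-free: five spikes,
  # final potential exactly zero
  p <- lif_params(Cm = 1, gl = 0, Vth = 1)
  tr <- lif_simulate(periodic_train(10, 0.5, g), p, g)
  expect_equal(sum(tr$S), 5)
  expect_equal(tr$V[g$n_steps], 0)

  # events outside the window or a mismatched grid are rejected
  expect_error(spike_train(1.5, 1, g), "t_window")
  expect_error(spike_train(0, 1, g), "t_window")
  expect_error(lif_simulate(spike_train(0.5, 1, sim_grid(0.01, 2)), p, g),
               "aligned")
})

test_that("post-spike reset follows the linear and zero rules", {
  lin <- lif_params(Vth = 2, reset_mode = "linear")
  zer <- lif_params(Vth = 2, reset_mode = "zero")
  expect_equal(apply_reset(3, TRUE, lin), 1)    # H - Vth
  expect_equal(apply_reset(3, TRUE, zer), 0)    # Vreset
  expect_equal(apply_reset(0.8, FALSE, lin), 0.8)
  expect_equal(apply_reset(0.8, FALSE, zer), 0.8)
})

test_that("a step with a pathological amplitude emits one spike and carries the surplus", {
  g <- sim_grid(0.01, 0.1)
  p <- lif_params(Cm = 1, gl = 0, Vth = 1, reset_mode = "linear")
  tr <- lif_simulate(spike_train(0.05, 2.5, g), p, g)
  # one spike at the event step; the surplus 1.5 re-crosses threshold at
  # the next step, then 0.5 remains
  expect_equal(tr$S[5:7], c(1L, 1L, 0L))
  expect_equal(tr$V[5], 1.5)
  expect_equal(tr$V[g$n_steps], 0.5)
  # reset-to-zero discards the surplus: one spike only
  tz <- lif_simulate(spike_train(0.05, 2.5, g),
                     lif_params(Cm = 1, gl = 0, Vth = 1,
                                reset_mode = "zero"), g)
  expect_equal(sum(tz$S), 1)
})

test_that("soft-reset charge conservation holds exactly without leak", {
  g <- sim_grid(0.01, 2)
  set.seed(42)
  for (i in 1:200) {
    Cm <- runif(1, 0.5, 2)
    p <- lif_params(Cm = Cm, gl = 0, Vth = runif(1, 0.5, 1.5),
                    reset_mode = "linear")
    k <- sample(1:40, 1)
    tr_in <- spike_train(runif(k, 0.01, 2), runif(k, 0.05, 1.2), g)
    tr <- lif_simulate(tr_in, p, g)
    lhs <- tr$V[g$n_steps] + p$Vth * sum(tr$S)
    expect_equal(lhs, sum(tr_in$amplitudes) / Cm, tolerance = 1e-9)
  }
})

test_that("reset-to-zero never out-fires the linear reset and rates are monotone in input rate", {
  g <- sim_grid(0.01, 2)
  set.seed(11)
  for (i in 1:30) {
    w <- runif(1, 0.1, 0.9); f <- runif(1, 1, 30); gl <- runif(1, 0, 3)
    tr_in <- periodic_train(f, w, g)
    n_lin <- sum(lif_simulate(tr_in, lif_params(gl = gl, reset_mode = "linear"), g)$S)
    n_zer <- sum(lif_simulate(tr_in, lif_params(gl = gl, reset_mode = "zero"), g)$S)
    expect_lte(n_zer, n_lin)
  }
  # output count never decreases as the event rate rises
  for (gl in c(0, 1, 3)) {
    p <- lif_params(gl = gl)
    counts <- vapply(1:30, function(f)
      sum(lif_simulate(periodic_train(f, 0.5, g), p, g)$S), 0L)
    expect_false(is.unsorted(counts))
  }
})

test_that("the coarse grid agrees with a fine Euler integrator on spike counts", {
  t_window <- 2
  g <- sim_grid(0.01, t_window)
  set.seed(7)
  n_cases <- 100
  cases <- data.frame(w = runif(n_cases, 0.1, 0.9),
                      f = runif(n_cases, 1, 30),
                      gl = runif(n_cases, 0, 3))
  coarse <- vapply(seq_len(n_cases), function(i) {
    sum(lif_simulate(periodic_train(cases$f[i], cases$w[i], g),
                     lif_params(Cm = 1, gl = cases$gl[i], Vth = 1), g)$S)
  }, 0L)
  fine_dt <- 1e-5
  charge <- periodic_charge_matrix(cases$f, cases$w, t_window, fine_dt)
  fine <- euler_spike_counts(charge, 1, cases$gl, 1, fine_dt)
  expect_gte(mean(fine == coarse), 0.99)
})

test_that("membrane traces and spike trains export to CSV", {
  g <- sim_grid(0.01, 0.5)
  tr <- lif_simulate(periodic_train(10, 0.6, g), lif_params(), g)
  f1 <- tempfile(fileext = ".csv")
  write_membrane_trace_csv(tr, f1)
  got <- read.csv(f1)
  expect_identical(names(got), c("time", "H", "V", "S"))
  expect_equal(got$V, tr$V)

  f2 <- tempfile(fileext = ".csv")
  write_spike_train_csv(tr$output_train, f2)
  got2 <- read.csv(f2)
  expect_identical(names(got2), c("time", "amplitude"))
  expect_equal(nrow(got2), sum(tr$S))
})
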