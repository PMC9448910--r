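# Shared helpers for the lifmap test suite. The fine-grid integrator below
# is a deliberately independent oracle: forward-Euler leak (not the exact
# exponential the package uses), run at a step small enough that the
# first-order error is negligible.

periodic_train <- function(f, amplitude, grid) {
  n <- floor(grid$t_window * f + 1e-9)
  if (n < 1) return(spike_train(numeric(0), grid = grid))
  spike_train(seq_len(n) / f, amplitude, grid)
}

# Euler integration of several neurons at once (cases in columns).
# charge: n_steps x M matrix; returns per-case spike counts.
euler_spike_counts <- function(charge, Cm, gl, Vth, dt,
                               reset_mode = "linear") {
  n <- nrow(charge); M <- ncol(charge)
  Cm <- rep_len(Cm, M); gl <- rep_len(gl, M)
  leak <- 1 - dt * gl / Cm
  V <- numeric(M)
  counts <- integer(M)
  linear <- identical(reset_mode, "linear")
  for (t in seq_len(n)) {
    H <- V * leak + charge[t, ] / Cm
    fired <- H >= Vth
    counts <- counts + fired
    V <- if (linear) H - Vth * fired else ifelse(fired, 0, H)
  }
  counts
}

# charge matrix for periodic trains on an arbitrary grid resolution
periodic_charge_matrix <- function(fs, ws, t_window, dt) {
  n_steps <- round(t_window / dt)
  charge <- matrix(0, n_steps, length(fs))
  for (i in seq_along(fs)) {
    k <- floor(t_window * fs[i] + 1e-9)
    if (k < 1) next
    st <- pmin(pmax(ceiling(seq_len(k) / fs[i] / dt - 0.5), 1), n_steps)
    for (s in st) charge[s, i] <- charge[s, i] + ws[i]
  }
  charge
}

# plain nested-loop 2-D cross-correlation with zero padding (stride 1),
# independent of the package's conv machinery
naive_xcorr <- function(img, kernel, pad) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  out <- matrix(0, H + 2 * pad - kh + 1, W + 2 * pad - kw + 1)
  padded <- matrix(0, H + 2 * pad, W + 2 * pad)
  padded[pad + seq_len(H), pad + seq_len(W)] <- img
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    out[i, j] <- sum(padded[i:(i + kh - 1), j:(j + kw - 1)] * kernel)
  }
  out
}
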