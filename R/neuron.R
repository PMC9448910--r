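#' Biophysical parameters of a leaky integrate-and-fire neuron
#'
#' The membrane obeys `Cm dV/dt + gl (V - V0) = I_inj(t)` with leak
#' conductance `gl = 1/Rm` and membrane time constant `tau_m = Cm / gl`
#' (defined only for `gl > 0`). Input is a train of Dirac impulses; each
#' impulse of amplitude `w` steps the potential by `w / Cm`. When the
#' pre-reset potential `H` reaches the threshold `Vth` the neuron emits one
#' unit-amplitude spike and resets:
#' \describe{
#'   \item{`"linear"`}{soft reset / reset-by-subtraction, `V = H - Vth`; the
#'     surplus above threshold is retained.}
#'   \item{`"zero"`}{reset-to-zero, `V = Vreset`; the surplus is discarded.}
#' }
#'
#' @param Cm Membrane capacitance (charge per unit potential), `> 0`.
#' @param gl Leak conductance, `>= 0`. `gl = 0` gives a non-leaky integrator.
#' @param Vth Spiking threshold potential, `> 0`.
#' @param Vreset Reset potential (default 0, used by `"zero"` mode).
#' @param V0 Resting potential (default 0).
#' @param reset_mode `"linear"` (soft reset) or `"zero"`.
#' @return An object of class `lif_params`.
#' @examples
#' lif_params(Cm = 1, gl = 3, Vth = 1)
#' @export
lif_params <- function(Cm = 1, gl = 0, Vth = 1, Vreset = 0, V0 = 0,
                       reset_mode = c("linear", "zero")) {
  reset_mode <- match.arg(reset_mode)
  if (!is.numeric(Cm) || any(Cm <= 0) || !all(is.finite(Cm)))
    stop("`Cm` must be positive", call. = FALSE)
  if (!is.numeric(gl) || any(gl < 0) || !all(is.finite(gl)))
    stop("`gl` must be non-negative", call. = FALSE)
  if (!is.numeric(Vth) || any(Vth <= 0))
    stop("`Vth` must be positive", call. = FALSE)
  structure(list(Cm = Cm, gl = gl, Vth = Vth, Vreset = Vreset, V0 = V0,
                 reset_mode = reset_mode),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  tau <- if (all(x$gl > 0)) paste0(signif(x$Cm / x$gl, 4), " s") else "Inf"
  cat(sprintf("<lif_params> Cm = %s, gl = %s, Vth = %g, reset = %s, tau_m = %s\n",
              paste(signif(x$Cm, 4), collapse = ","),
              paste(signif(x$gl, 4), collapse = ","),
              x$Vth, x$reset_mode, tau))
  invisible(x)
}

#' Membrane time constant
#' @param params A [lif_params()].
#' @return `Cm / gl`, or `Inf` when `gl = 0`.
#' @export
tau_m <- function(params) {
  stopifnot(inherits(params, "lif_params"))
  ifelse(params$gl > 0, params$Cm / params$gl, Inf)
}

#' Closed-form subthreshold potential under periodic impulse input
#'
#' For a periodic train of impulses of amplitude `weight` and period
#' `period`, with no threshold applied, the membrane potential immediately
#' after the n-th impulse is the geometric sum
#' `(weight / Cm) * sum_{j=0}^{n-1} exp(-j * period / tau_m)`,
#' i.e. `(weight / Cm) * (1 - r^n) / (1 - r)` with `r = exp(-period/tau_m)`;
#' for `gl = 0` the sum is `n * weight / Cm`.
#'
#' @param params A [lif_params()] (only `Cm`, `gl` are used).
#' @param weight Impulse amplitude.
#' @param period Inter-impulse interval in seconds, `> 0`.
#' @param n Impulse count, `>= 1`.
#' @return Membrane potential just after the n-th impulse.
#' @examples
#' closed_form_potential(lif_params(Cm = 1, gl = 0), weight = 0.5,
#'                       period = 0.1, n = 4) # 2
#' @export
closed_form_potential <- function(params, weight, period, n) {
  stopifnot(inherits(params, "lif_params"))
  if (!is.numeric(n) || any(n < 1) || any(n != round(n)))
    stop("`n` must be a positive integer", call. = FALSE)
  if (!is.numeric(period) || any(period <= 0))
    stop("`period` must be positive", call. = FALSE)
  if (all(params$gl == 0)) return(n * weight / params$Cm)
  r <- exp(-period / tau_m(params))
  (weight / params$Cm) * (1 - r^n) / (1 - r)
}

#' Post-spike reset rule
#'
#' @param H Pre-reset membrane potential.
#' @param fired Logical; did the neuron cross threshold at this step?
#' @param params A [lif_params()].
#' @return Post-reset potential: `H` when not fired; `H - Vth` in linear
#'   mode; `Vreset` in zero mode.
#' @export
apply_reset <- function(H, fired, params) {
  stopifnot(inherits(params, "lif_params"))
  if (params$reset_mode == "linear") {
    ifelse(fired, H - params$Vth, H)
  } else {
    ifelse(fired, params$Vreset, H)
  }
}

# Core grid integrator, vectorised over neurons (columns).
#
# charge: n_steps x M matrix of injected charge per step (sum of event
# amplitudes). Cm, gl may be scalars or length-M vectors. Scheme: exact
# exponential decay over one step, then instantaneous charge injection --
# exact for Dirac-train input currents with events on grid steps. At most
# one spike per step; in linear mode any surplus (H >= 2 Vth) carries over.
lif_engine <- function(charge, Cm, gl, Vth, dt, reset_mode = "linear",
                       Vreset = 0, keep_trace = FALSE) {
  charge <- as.matrix(charge)
  n <- nrow(charge)
  M <- ncol(charge)
  Cm <- rep_len(Cm, M)
  gl <- rep_len(gl, M)
  decay <- exp(-dt * gl / Cm)
  jump <- sweep(charge, 2L, Cm, "/")
  V <- numeric(M)
  S <- matrix(FALSE, n, M)
  H_tr <- if (keep_trace) matrix(0, n, M)
  V_tr <- if (keep_trace) matrix(0, n, M)
  linear <- identical(reset_mode, "linear")
  for (t in seq_len(n)) {
    H <- V * decay + jump[t, ]
    fired <- H >= Vth
    S[t, ] <- fired
    V <- if (linear) H - Vth * fired else ifelse(fired, Vreset, H)
    if (keep_trace) {
      H_tr[t, ] <- H
      V_tr[t, ] <- V
    }
  }
  list(S = S, V_final = V, H = H_tr, V = V_tr)
}

#' Simulate a LIF neuron on a spike-train input
#'
#' Runs the discrete membrane update on the grid: per step the potential
#' decays exactly (`V <- V * exp(-dt * gl / Cm)`), then the step's summed
#' event amplitude is injected (`V <- V + amplitude / Cm`) giving the
#' pre-reset potential `H`; if `H >= Vth` one unit-amplitude output spike is
#' emitted and the reset rule of `params$reset_mode` is applied. The decay +
#' injection scheme is exact for Dirac-train inputs, not an Euler
#' approximation. The initial potential is `Vreset`.
#'
#' @param input A [spike_train()] aligned to `grid` (events off-grid or
#'   outside `(0, t_window]` are an error).
#' @param params A [lif_params()].
#' @param grid A [sim_grid()]; defaults to the input train's grid.
#' @return An object of class `membrane_trace`: per-step `time`, `H`
#'   (pre-reset potential), `V` (post-reset potential), `S` (0/1 spike
#'   indicator), plus `output_train` (the emitted unit-amplitude
#'   [spike_train()]), `params` and `grid`.
#' @examples
#' g <- sim_grid(0.01, 1)
#' tr <- lif_simulate(spike_train(c(0.2, 0.5), 1, g), lif_params(Vth = 1), g)
#' n_spikes(tr$output_train) # 2
#' @export
lif_simulate <- function(input, params, grid = input$grid) {
  stopifnot(inherits(input, "spike_train"), inherits(params, "lif_params"),
            inherits(grid, "sim_grid"))
  if (!grids_identical(input$grid, grid))
    stop("input train is not aligned to the simulation grid", call. = FALSE)
  charge <- train_to_steps(input)
  res <- lif_engine(matrix(charge, ncol = 1), params$Cm, params$gl,
                    params$Vth, grid$dt, params$reset_mode, params$Vreset,
                    keep_trace = TRUE)
  S <- as.integer(res$S[, 1L])
  out <- structure(
    list(time = seq_len(grid$n_steps) * grid$dt,
         H = res$H[, 1L], V = res$V[, 1L], S = S,
         output_train = steps_to_train(as.numeric(S), grid),
         params = params, grid = grid),
    class = "membrane_trace")
  out
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("<membrane_trace> %d steps, %d output spikes, final V = %.4g\n",
              length(x$time), sum(x$S), x$V[length(x$V)]))
  invisible(x)
}

#' @export
as.data.frame.membrane_trace <- function(x, ...) {
  data.frame(time = x$time, H = x$H, V = x$V, S = x$S)
}

#' Write a membrane trace to CSV (columns: time, H, V, S)
#'
#' @param trace A `membrane_trace` from [lif_simulate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_membrane_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "membrane_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
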