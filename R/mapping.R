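#' Parameters of a rectified-linear artificial neuron
#'
#' Output contract: `y = slope * max(0, sum(weights * x) + bias)`.
#'
#' @param weights Numeric weight vector.
#' @param bias Bias term. The LIF mapping supports `bias <= 0` (a
#'   non-positive bias corresponds to a positive minimum firing frequency).
#' @param slope Positive slope of the activation function.
#' @return An object of class `relu_params`.
#' @export
relu_params <- function(weights, bias = 0, slope = 1) {
  if (!is.numeric(weights) || length(weights) < 1L)
    stop("`weights` must be a numeric vector", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("`slope` must be a single positive number", call. = FALSE)
  if (!is.numeric(bias) || length(bias) != 1L || !is.finite(bias))
    stop("`bias` must be a single finite number", call. = FALSE)
  structure(list(weights = as.numeric(weights), bias = bias, slope = slope),
            class = "relu_params")
}

#' @export
print.relu_params <- function(x, ...) {
  cat(sprintf("<relu_params> %d weights (sum %.4g), bias = %.4g, slope = %g\n",
              length(x$weights), sum(x$weights), x$bias, x$slope))
  invisible(x)
}

#' Evaluate a ReLU neuron
#' @param relu A [relu_params()].
#' @param x Input vector (e.g. input frequencies in Hz).
#' @return `slope * max(0, sum(weights * x) + bias)`.
#' @export
relu_output <- function(relu, x) {
  stopifnot(inherits(relu, "relu_params"))
  relu$slope * max(0, sum(relu$weights * x) + relu$bias)
}

#' Configuration of the ReLU/LIF parameter mapping
#'
#' Fixes the free choices of the mapping: the spiking threshold `v_th` used
#' on the LIF side and the time window `t_window` used for finite-horizon
#' minimum-frequency calculations. The bias mapping is defined only while
#' `0 < sum(weights) < v_th * Cm` (the logarithm argument stays in (0, 1)).
#'
#' @param v_th Spiking threshold for the LIF side, `> 0`.
#' @param t_window Time window in seconds, `> 0`.
#' @return An object of class `mapping_config`.
#' @export
mapping_config <- function(v_th = 1, t_window = 3) {
  if (!is.numeric(v_th) || length(v_th) != 1L || v_th <= 0)
    stop("`v_th` must be a single positive number", call. = FALSE)
  if (!is.numeric(t_window) || length(t_window) != 1L || t_window <= 0)
    stop("`t_window` must be a single positive number", call. = FALSE)
  structure(list(v_th = v_th, t_window = t_window), class = "mapping_config")
}

# shared validity check for the biased branch of the mapping
check_mapping_domain <- function(sw, Vth, Cm) {
  if (sw <= 0)
    stop("mapping-domain error: sum(weights) must be positive for a biased ",
         "neuron", call. = FALSE)
  if (sw >= Vth * Cm)
    stop("mapping-domain error: sum(weights) must be < Vth * Cm ",
         sprintf("(got %.4g >= %.4g)", sw, Vth * Cm), call. = FALSE)
  invisible(TRUE)
}

#' Map a ReLU neuron to a linear-reset LIF neuron
#'
#' The structural mapping of the two parameter sets. Weights pass through
#' unchanged (they ride in spike amplitudes). The activation slope fixes the
#' membrane capacitance, `Cm = 1 / (slope * v_th)`. A non-positive bias
#' fixes the leak conductance through the self-consistency requirement that
#' the ReLU zero-crossing frequency `-bias / sum(weights)` equals the LIF
#' neuron's asymptotic minimum firing frequency; in closed form
#' `gl = bias * Cm * log(1 - a) / sum(weights)` with
#' `a = sum(weights) / (v_th * Cm)`, so `bias = 0` maps to `gl = 0` and
#' larger `|bias|` to larger `gl`.
#'
#' @param relu A [relu_params()].
#' @param cfg A [mapping_config()].
#' @return An object of class `lif_mapping`: list with `params` (a linear
#'   reset [lif_params()]), `weights` (unchanged), `relu`, and `cfg`.
#' @seealso [lif_to_relu()] for the inverse, [min_firing_frequency()].
#' @examples
#' m <- relu_to_lif(relu_params(c(0.3, 0.2), bias = -2.1640, slope = 1),
#'                  mapping_config(v_th = 1))
#' m$params$gl # ~ 3
#' @export
relu_to_lif <- function(relu, cfg = mapping_config()) {
  stopifnot(inherits(relu, "relu_params"), inherits(cfg, "mapping_config"))
  Vth <- cfg$v_th
  Cm <- 1 / (relu$slope * Vth)
  sw <- sum(relu$weights)
  if (relu$bias > 0)
    stop("unsupported-bias error: the LIF mapping requires bias <= 0",
         call. = FALSE)
  if (relu$bias == 0) {
    gl <- 0
  } else {
    check_mapping_domain(sw, Vth, Cm)
    a <- sw / (Vth * Cm)
    gl <- relu$bias * Cm * log(1 - a) / sw
  }
  structure(list(params = lif_params(Cm = Cm, gl = gl, Vth = Vth,
                                     reset_mode = "linear"),
                 weights = relu$weights, relu = relu, cfg = cfg),
            class = "lif_mapping")
}

#' @export
print.lif_mapping <- function(x, ...) {
  cat("<lif_mapping>\n  ")
  print(x$params)
  cat(sprintf("  %d weights pass through unchanged (sum %.4g)\n",
              length(x$weights), sum(x$weights)))
  invisible(x)
}

#' Map a linear-reset LIF neuron back to a ReLU neuron
#'
#' Inverse of [relu_to_lif()]: `slope = 1 / (Vth * Cm)` and
#' `bias = gl * sum(weights) / (Cm * log(1 - a))` (non-positive), the sign
#' convention under which the ReLU zero-crossing frequency
#' `-bias / sum(weights)` equals the asymptotic minimum firing frequency.
#' The round trip `lif_to_relu(relu_to_lif(.))` is the identity to within
#' floating-point error. The attribute `bias_printed` carries the
#' alternative algebraic variant `-(sum(weights) * gl / Cm) * log(1 - a)`
#' (opposite sign, different magnitude) for comparison.
#'
#' @param params A linear-reset [lif_params()].
#' @param weights Numeric weight vector (passes through unchanged).
#' @param cfg A [mapping_config()]; its `v_th` must match `params$Vth`.
#' @return A [relu_params()] with attribute `bias_printed`.
#' @export
lif_to_relu <- function(params, weights, cfg = mapping_config(v_th = params$Vth)) {
  stopifnot(inherits(params, "lif_params"))
  if (params$reset_mode != "linear")
    stop("the ReLU mapping is defined for linear (soft) reset only",
         call. = FALSE)
  Vth <- params$Vth
  Cm <- params$Cm
  sw <- sum(weights)
  k <- 1 / (Vth * Cm)
  if (params$gl == 0) {
    b <- 0
    b_printed <- 0
  } else {
    check_mapping_domain(sw, Vth, Cm)
    a <- sw / (Vth * Cm)
    b <- params$gl * sw / (Cm * log(1 - a))
    b_printed <- -(sw * params$gl / Cm) * log(1 - a)
  }
  out <- relu_params(weights, bias = b, slope = k)
  attr(out, "bias_printed") <- b_printed
  out
}

#' Minimum input frequency that can excite an action potential
#'
#' For equal-frequency inputs with combined amplitude `sum(weights)`, the
#' analytic threshold frequency below which the neuron cannot reach `Vth`
#' within the time window:
#' `f_min = -1 / (tau_m * log(1 - A))` with
#' `A = (sum(weights) / (Vth * Cm)) * (1 - exp(-t_window / tau_m))` for
#' `gl > 0`, and the leak-free limit `Vth * Cm / (sum(weights) * t_window)`
#' for `gl = 0` (the first spike needs `Vth * Cm / sum(weights)` inputs
#' inside the window). `f_min` increases with `gl` and diverges as
#' `sum(weights) -> Vth * Cm` from below in the infinite-window limit.
#'
#' @param params A linear-reset [lif_params()].
#' @param weights Numeric weight vector.
#' @param t_window Time window in seconds.
#' @return Frequency in Hz.
#' @seealso [min_firing_frequency_sim()] for the simulate-based bisection
#'   companion used as its oracle.
#' @export
min_firing_frequency <- function(params, weights, t_window) {
  stopifnot(inherits(params, "lif_params"))
  if (params$reset_mode != "linear")
    stop("minimum firing frequency is defined for linear reset", call. = FALSE)
  sw <- sum(weights)
  if (sw <= 0)
    stop("mapping-domain error: sum(weights) must be positive", call. = FALSE)
  if (params$gl == 0) return(params$Vth * params$Cm / (sw * t_window))
  tm <- tau_m(params)
  A <- (sw / (params$Vth * params$Cm)) * (1 - exp(-t_window / tm))
  if (A >= 1)
    stop("mapping-domain error: sum(weights) * (1 - exp(-t_window/tau_m)) ",
         "must be < Vth * Cm", call. = FALSE)
  -1 / (tm * log(1 - A))
}

#' Bisection search for the minimum firing frequency on the simulator
#'
#' Companion to [min_firing_frequency()]: finds, by bisection on the input
#' frequency, the smallest frequency at which a periodic input train of
#' combined amplitude `sum(weights)` drives at least one output spike in
#' the window. Because the input is snapped to the grid and truncated to
#' whole periods, the simulated value agrees with the analytic one to about
#' one grid frequency resolution (`1 / t_window`).
#'
#' @param params A linear-reset [lif_params()].
#' @param weights Numeric weight vector.
#' @param grid A [sim_grid()].
#' @param f_upper Upper bracket in Hz (default the grid sampling limit).
#' @param tol Bisection tolerance in Hz.
#' @return Frequency in Hz (`NA` if even `f_upper` never fires).
#' @export
min_firing_frequency_sim <- function(params, weights, grid,
                                     f_upper = 1 / grid$dt, tol = 1e-3) {
  stopifnot(inherits(params, "lif_params"), inherits(grid, "sim_grid"))
  sw <- sum(weights)
  fires <- function(f) {
    n <- floor(grid$t_window * f + 1e-9)
    if (n < 1) return(FALSE)
    tr <- spike_train(seq_len(n) / f, sw, grid)
    sum(lif_simulate(tr, params, grid)$S) >= 1
  }
  lo <- 1 / grid$t_window / 2 # below one period per window: cannot fire
  hi <- f_upper
  if (!fires(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Predicted output frequency of a mapped LIF neuron
#'
#' Two analytic predictions of the output spike frequency are returned:
#' \describe{
#'   \item{`exact`}{for equal-frequency inputs: `n_star` is the smallest
#'     impulse count at which the closed-form subthreshold potential (at
#'     combined amplitude `sum(weights)` and period `1/f`) reaches `Vth`,
#'     and `f_out = f / n_star`. This describes the first-spike recurrence
#'     (and, exactly, the reset-to-zero neuron's rate); with linear reset
#'     and leak the realised rate can exceed it because the surplus carries
#'     over. `NA` when the inputs differ in frequency; 0 when the threshold
#'     is unreachable within the window.}
#'   \item{`approx`}{the proportional law for general inputs:
#'     `f_out = max(0, sum(weights * f_in)) / (Vth * Cm)`.}
#' }
#'
#' @param f_in Per-input frequencies in Hz (scalar or vector, one per
#'   weight).
#' @param weights Numeric weight vector.
#' @param params A linear-reset [lif_params()].
#' @param t_window Time window used to cap the spike-count search.
#' @return List with `exact`, `approx` and `n_star`.
#' @export
predicted_output_frequency <- function(f_in, weights, params, t_window = 3) {
  stopifnot(inherits(params, "lif_params"))
  f_in <- rep_len(as.numeric(f_in), length(weights))
  sw <- sum(weights)
  approx <- max(0, sum(weights * f_in)) / (params$Vth * params$Cm)
  exact <- NA_real_
  n_star <- NA_integer_
  if (length(unique(round(f_in, 12))) == 1L) {
    f <- f_in[1L]
    exact <- 0
    if (f > 0 && sw > 0) {
      n_max <- max(1L, floor(t_window * f + 1e-9))
      n <- seq_len(n_max)
      V <- closed_form_potential(lif_params(Cm = params$Cm, gl = params$gl,
                                            Vth = params$Vth),
                                 sw, 1 / f, n)
      hit <- which(V >= params$Vth)
      if (length(hit)) {
        n_star <- hit[1L]
        exact <- f / n_star
      }
    }
  }
  list(exact = exact, approx = approx, n_star = n_star)
}

#' Export a parameter-mapping report as JSON
#'
#' Serialises the ReLU-side parameters, the mapped LIF parameters, the
#' validity flags and the minimum firing frequency computed both from the
#' analytic formula and from the bias zero-crossing.
#'
#' @param relu A [relu_params()].
#' @param cfg A [mapping_config()].
#' @param path Optional output path; when `NULL` the report list is
#'   returned without writing.
#' @return The report list, invisibly when written.
#' @export
mapping_report <- function(relu, cfg = mapping_config(), path = NULL) {
  m <- relu_to_lif(relu, cfg)
  inv <- lif_to_relu(m$params, m$weights, cfg)
  sw <- sum(relu$weights)
  f_min <- if (m$params$gl > 0 || sw > 0)
    tryCatch(min_firing_frequency(m$params, m$weights, cfg$t_window),
             error = function(e) NA_real_) else NA_real_
  rep <- list(
    relu = list(weights = relu$weights, bias = relu$bias, slope = relu$slope),
    lif = list(Cm = m$params$Cm, gl = m$params$gl, Vth = m$params$Vth,
               reset_mode = m$params$reset_mode),
    valid_bias_domain = sw > 0 && sw < cfg$v_th * m$params$Cm,
    bias_printed = attr(inv, "bias_printed"),
    f_min_analytic = f_min,
    f_min_zero_crossing = if (relu$bias < 0) -relu$bias / sw else 0,
    round_trip_bias = inv$bias,
    t_window = cfg$t_window
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
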