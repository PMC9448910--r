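#' Experiment run configuration
#'
#' Bundles the numerical choices every experiment needs: the grid (`dt`,
#' `t_window`), the coding ceiling `f_max`, the mapping threshold `v_th`
#' and the seed for any randomness. Defaults: `dt` = 0.01 s,
#' `t_window` = 3 s, `f_max` = 10 Hz, `v_th` = 1.
#'
#' @param dt Time step in seconds.
#' @param t_window Time window in seconds.
#' @param f_max Maximum coding frequency in Hz.
#' @param v_th Spiking threshold.
#' @param seed Integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(dt = 0.01, t_window = 3, f_max = 10, v_th = 1,
                       seed = 1) {
  grid <- sim_grid(dt, t_window)
  structure(list(dt = dt, t_window = t_window, f_max = f_max, v_th = v_th,
                 seed = as.integer(seed), grid = grid,
                 code = rate_code(f_max, grid),
                 mapping = mapping_config(v_th, t_window)),
            class = "run_config")
}

# decoded output frequency of a single mapped neuron under equal-frequency
# periodic inputs with the given weights (inputs superposed by amplitude)
simulate_transfer_point <- function(f, weights, params, grid) {
  sw <- sum(weights)
  n <- floor(grid$t_window * f + 1e-9)
  tr <- if (n >= 1) spike_train(seq_len(n) / f, sw, grid)
        else spike_train(numeric(0), grid = grid)
  sum(lif_simulate(tr, params, grid)$S) / grid$t_window
}

experiment_transfer_curve <- function(cfg, weights = c(0.3, 0.2), gl = 3,
                                      f_range = 1:30) {
  lin <- lif_params(Cm = 1, gl = gl, Vth = cfg$v_th, reset_mode = "linear")
  zer <- lif_params(Cm = 1, gl = gl, Vth = cfg$v_th, reset_mode = "zero")
  relu <- lif_to_relu(lin, weights, cfg$mapping)
  out <- data.frame(f_in = f_range)
  out$relu <- vapply(f_range, function(f)
    relu_output(relu, rep(f, length(weights))), 0)
  out$linear <- vapply(f_range, simulate_transfer_point, 0,
                       weights = weights, params = lin, grid = cfg$grid)
  out$zero <- vapply(f_range, simulate_transfer_point, 0,
                     weights = weights, params = zer, grid = cfg$grid)
  pred <- lapply(f_range, function(f)
    predicted_output_frequency(rep(f, length(weights)), weights, lin,
                               cfg$t_window))
  out$pred_exact <- vapply(pred, function(p) p$exact, 0)
  out$pred_approx <- vapply(pred, function(p) p$approx, 0)
  attr(out, "bias") <- relu$bias
  out
}

experiment_fmin_sweep <- function(cfg, weights = c(0.3, 0.2),
                                  gl_range = seq(0.5, 5, by = 0.5)) {
  out <- data.frame(gl = gl_range)
  out$f_min_analytic <- vapply(gl_range, function(g)
    min_firing_frequency(lif_params(Cm = 1, gl = g, Vth = cfg$v_th),
                         weights, cfg$t_window), 0)
  out$f_min_sim <- vapply(gl_range, function(g)
    min_firing_frequency_sim(lif_params(Cm = 1, gl = g, Vth = cfg$v_th),
                             weights, cfg$grid), 0)
  out$bias <- vapply(gl_range, function(g)
    lif_to_relu(lif_params(Cm = 1, gl = g, Vth = cfg$v_th), weights,
                cfg$mapping)$bias, 0)
  out
}

experiment_slope_sweep <- function(cfg, weights = c(0.3, 0.2),
                                   Cm_values = c(0.5, 1, 2, 4),
                                   f_range = 1:30) {
  x <- vapply(f_range, function(f) sum(weights) * f, 0)
  rows <- lapply(Cm_values, function(Cm) {
    p <- lif_params(Cm = Cm, gl = 0, Vth = cfg$v_th)
    f_o <- vapply(f_range, simulate_transfer_point, 0, weights = weights,
                  params = p, grid = cfg$grid)
    fit <- stats::lm(f_o ~ x)
    data.frame(Cm = Cm, slope_sim = unname(stats::coef(fit)[2L]),
               slope_theory = 1 / (cfg$v_th * Cm))
  })
  do.call(rbind, rows)
}

# run a converted fixture network and its reference over a batch of
# random inputs; returns matrices of output frequencies and activations
compare_network <- function(spec, cfg, n_inputs = 20,
                            collect_hidden = FALSE) {
  model <- convert(spec, cfg$mapping, cfg$grid, cfg$code)
  n_in <- prod(spec$input_shape)
  n_out <- prod(spec$shapes[[length(spec$shapes)]])
  xs <- with_seed(cfg$seed + 1000L,
                  lapply(seq_len(n_inputs), function(i) {
                    v <- runif(n_in)
                    if (length(spec$input_shape) > 1L)
                      array(v, dim = spec$input_shape) else v
                  }))
  f_snn <- matrix(0, n_inputs, n_out)
  f_ann <- matrix(0, n_inputs, n_out)
  lab_snn <- integer(n_inputs)
  lab_ann <- integer(n_inputs)
  hid_snn <- hid_ann <- NULL
  hid_layer <- if (collect_hidden) pick_hidden_layer(spec)
  if (collect_hidden && !is.null(hid_layer)) {
    n_hid <- prod(spec$shapes[[hid_layer]])
    hid_snn <- matrix(0, n_inputs, n_hid)
    hid_ann <- matrix(0, n_inputs, n_hid)
  }
  for (i in seq_len(n_inputs)) {
    rs <- snn_infer(model, xs[[i]], keep_layers = collect_hidden)
    ra <- ann_infer(spec, xs[[i]], cfg$f_max, keep_layers = collect_hidden)
    f_snn[i, ] <- rs$frequencies
    f_ann[i, ] <- ra$activations
    lab_snn[i] <- rs$label
    lab_ann[i] <- ra$label
    if (!is.null(hid_snn)) {
      hid_snn[i, ] <- tensor_frequencies(rs$layers[[hid_layer]])
      hid_ann[i, ] <- as.numeric(ra$layers[[hid_layer]])
    }
  }
  list(f_snn = f_snn, f_ann = f_ann, labels_snn = lab_snn,
       labels_ann = lab_ann, inputs = xs, hidden_snn = hid_snn,
       hidden_ann = hid_ann, model = model)
}

# last layer before the readout that produces activations worth
# correlating (prefers the layer feeding the final dense readout)
pick_hidden_layer <- function(spec) {
  n <- length(spec$layers)
  if (n < 2L) return(NULL)
  n - 1L
}

experiment_network_compare <- function(cfg, arch = NULL, n_inputs = 20) {
  fc <- if (is.null(arch))
    fixture_config(cfg$seed, input_shape = 16)
  else fixture_config(cfg$seed, arch = arch$arch,
                      input_shape = arch$input_shape)
  spec <- gen_network(fc)
  cmp <- compare_network(spec, cfg, n_inputs)
  rep <- frequency_error_report(as.numeric(cmp$f_snn),
                                as.numeric(cmp$f_ann),
                                cfg$t_window, cfg$f_max)
  ag <- agreement(cmp$labels_ann, cmp$labels_snn,
                  ncol(cmp$f_snn))
  list(table = data.frame(input = rep(seq_len(nrow(cmp$f_snn)),
                                      ncol(cmp$f_snn)),
                          unit = rep(seq_len(ncol(cmp$f_snn)),
                                     each = nrow(cmp$f_snn)),
                          f_snn = as.numeric(cmp$f_snn),
                          f_ann = as.numeric(cmp$f_ann)),
       report = rep, agreement = ag$rate, compare = cmp)
}

experiment_error_vs_T <- function(cfg, T_values = c(1, 2, 5, 10),
                                  n_inputs = 10) {
  fc <- fixture_config(cfg$seed, input_shape = 16)
  spec <- gen_network(fc)
  rows <- lapply(T_values, function(T) {
    cfgT <- run_config(cfg$dt, T, cfg$f_max, cfg$v_th, cfg$seed)
    cmp <- compare_network(spec, cfgT, n_inputs)
    err <- abs(cmp$f_snn - cmp$f_ann)
    data.frame(T = T, max_error = max(err), mean_error = mean(err),
               bound = 1 / T)
  })
  do.call(rbind, rows)
}

#' Run a named experiment and (optionally) write its report files
#'
#' Available experiments:
#' \describe{
#'   \item{`transfer_curve`}{input-output frequency curves of the mapped
#'     ReLU reference, the linear-reset LIF and the reset-to-zero LIF over
#'     a frequency sweep (plus the analytic exact/approximate
#'     predictions).}
#'   \item{`fmin_sweep`}{analytic vs simulated minimum firing frequency
#'     and the mapped bias as functions of the leak conductance.}
#'   \item{`slope_sweep`}{regressed input-output slope vs the theoretical
#'     `1/(Vth*Cm)` across membrane capacitances.}
#'   \item{`network_compare`}{converted fixture network vs its reference:
#'     per-unit frequencies, error report and label agreement.}
#'   \item{`error_vs_T`}{maximum output-frequency error as a function of
#'     coding time, against the `1/T` bound.}
#' }
#' When `out_dir` is given, the result table is written as CSV and a JSON
#' report (with the full resolved configuration echoed) alongside.
#'
#' @param name Experiment name.
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory.
#' @param ... Passed to the individual experiment (e.g. `weights`, `gl`,
#'   `f_range`, `T_values`, `n_inputs`).
#' @return The experiment result (a data frame, or a list with a `table`
#'   element), invisibly when written.
#' @export
run_experiment <- function(name = c("transfer_curve", "fmin_sweep",
                                    "slope_sweep", "network_compare",
                                    "error_vs_T"),
                           cfg = run_config(), out_dir = NULL, ...) {
  name <- match.arg(name)
  stopifnot(inherits(cfg, "run_config"))
  res <- switch(name,
    transfer_curve = experiment_transfer_curve(cfg, ...),
    fmin_sweep = experiment_fmin_sweep(cfg, ...),
    slope_sweep = experiment_slope_sweep(cfg, ...),
    network_compare = experiment_network_compare(cfg, ...),
    error_vs_T = experiment_error_vs_T(cfg, ...))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- if (is.data.frame(res)) res else res$table
    utils::write.csv(tab, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    echo <- list(experiment = name,
                 config = list(dt = cfg$dt, t_window = cfg$t_window,
                               f_max = cfg$f_max, v_th = cfg$v_th,
                               seed = cfg$seed),
                 package_version =
                   as.character(utils::packageVersion("lifmap")))
    if (!is.data.frame(res) && !is.null(res$agreement))
      echo$agreement <- res$agreement
    jsonlite::write_json(echo, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}
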