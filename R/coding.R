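#' Rate-coding scheme
#'
#' Frequency (rate) coding represents a real value `x` in `[0, 1]` as a
#' periodic spike train of frequency `x * f_max` within the time window.
#' The sampling ceiling is one spike per grid step, so the scheme requires
#' `1 / f_max >= dt` (at full scale, at least one step per period).
#'
#' @param f_max Maximum coding frequency in Hz, `> 0`.
#' @param grid A [sim_grid()].
#' @return An object of class `rate_code`.
#' @export
rate_code <- function(f_max = 10, grid = sim_grid()) {
  stopifnot(inherits(grid, "sim_grid"))
  if (!is.numeric(f_max) || length(f_max) != 1L || f_max <= 0)
    stop("`f_max` must be a single positive number", call. = FALSE)
  if (1 / f_max < grid$dt - 1e-12)
    stop("`f_max` exceeds the grid sampling limit 1/dt", call. = FALSE)
  structure(list(f_max = f_max, grid = grid), class = "rate_code")
}

#' @export
print.rate_code <- function(x, ...) {
  cat(sprintf("<rate_code> f_max = %g Hz on [0, %g] s (dt = %g s)\n",
              x$f_max, x$grid$t_window, x$grid$dt))
  invisible(x)
}

#' Encode a value as a periodic spike train
#'
#' Emits a unit-amplitude train at frequency `f = x * f_max`: spike times
#' `t_j = j / f` for `j = 1 .. floor(t_window * f)`, snapped to the nearest
#' grid step (ties toward the earlier step). `x = 0` yields an empty train;
#' the first spike falls at `1/f`, not at 0.
#'
#' @param x A value in `[0, 1]`.
#' @param code A [rate_code()].
#' @return A [spike_train()].
#' @examples
#' code <- rate_code(10, sim_grid(0.01, 3))
#' n_spikes(encode_rate(1, code))   # 30
#' n_spikes(encode_rate(0.5, code)) # 15
#' @export
encode_rate <- function(x, code) {
  stopifnot(inherits(code, "rate_code"))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("`x` must be a single value in [0, 1]", call. = FALSE)
  f <- x * code$f_max
  n <- floor(code$grid$t_window * f + 1e-9)
  if (n < 1) return(spike_train(numeric(0), grid = code$grid))
  spike_train((seq_len(n)) / f, 1, code$grid)
}

#' Decode a spike train to a frequency
#'
#' The rate readout `f' = N / T`: number of events divided by the coding
#' time. Quantisation bounds the readout error by `1 / T`.
#'
#' @param train A [spike_train()].
#' @param T Coding time in seconds, `> 0`; defaults to the train's window.
#' @return Frequency in Hz.
#' @export
decode_rate <- function(train, T = train$grid$t_window) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("`T` must be a single positive number", call. = FALSE)
  n_spikes(train) / T
}

#' Weighted superposition of presynaptic spike trains
#'
#' Synaptic weights are carried in event amplitudes: the superposed train
#' contains every event of every input train with its amplitude multiplied
#' by the source train's weight. Coincident events on one grid step are kept
#' as separate events; the simulator sums them on injection.
#'
#' @param trains List of [spike_train()]s sharing one grid.
#' @param weights Numeric vector, one weight per train.
#' @return A [spike_train()].
#' @export
weighted_sum_trains <- function(trains, weights) {
  if (!is.list(trains) || !all(vapply(trains, inherits, TRUE, "spike_train")))
    stop("`trains` must be a list of spike_train objects", call. = FALSE)
  if (length(trains) != length(weights))
    stop("`trains` and `weights` must have equal length", call. = FALSE)
  if (length(trains) == 0L)
    stop("at least one train is required", call. = FALSE)
  grid <- trains[[1L]]$grid
  for (tr in trains) {
    if (!grids_identical(tr$grid, grid))
      stop("all trains must share one grid", call. = FALSE)
  }
  times <- unlist(lapply(trains, `[[`, "times"), use.names = FALSE)
  amps <- unlist(Map(function(tr, w) tr$amplitudes * w, trains,
                     as.list(weights)), use.names = FALSE)
  spike_train(times, if (length(amps)) amps else numeric(0), grid)
}
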