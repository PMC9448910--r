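#' Spike train
#'
#' A spike train is an ordered sequence of timed, amplitude-tagged point
#' events (Dirac impulses) aligned to a [sim_grid()]. Amplitudes carry the
#' synaptic weights: a weighted superposition of unit-amplitude trains is a
#' train whose event amplitudes are the weights. Events sharing a grid step
#' are permitted; they superpose when injected into a neuron.
#'
#' @param times Numeric vector of event times in `(0, t_window]`. They are
#'   snapped to the nearest grid step (ties toward the earlier step).
#' @param amplitudes Numeric vector of event amplitudes (recycled if scalar).
#' @param grid The [sim_grid()] the events live on.
#' @return An object of class `spike_train` with fields `times` (snapped,
#'   sorted), `amplitudes` and `grid`.
#' @seealso [encode_rate()], [weighted_sum_trains()], [lif_simulate()]
#' @export
spike_train <- function(times = numeric(0), amplitudes = 1, grid) {
  stopifnot(inherits(grid, "sim_grid"))
  times <- as.numeric(times)
  amplitudes <- rep_len(as.numeric(amplitudes), length(times))
  if (length(times)) {
    steps <- snap_to_grid(times, grid)
    ord <- order(steps)
    steps <- steps[ord]
    amplitudes <- amplitudes[ord]
    times <- steps * grid$dt
  } else {
    steps <- integer(0)
  }
  structure(list(times = times, amplitudes = amplitudes, steps = steps,
                 grid = grid),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d events on [0, %g] s (dt = %g s)\n",
              length(x$times), x$grid$t_window, x$grid$dt))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Number of events in a spike train
#' @param train A [spike_train()].
#' @return Integer event count.
#' @export
n_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$times)
}

#' Per-step amplitude vector of a spike train
#'
#' Bins the train onto its grid: element `s` is the summed amplitude of all
#' events snapped to step `s`. This is the injected-charge view used by the
#' simulator (charge per step = amplitude, potential jump = amplitude / Cm).
#'
#' @param train A [spike_train()].
#' @return Numeric vector of length `n_steps`.
#' @export
train_to_steps <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  out <- numeric(train$grid$n_steps)
  if (length(train$steps)) {
    agg <- rowsum(train$amplitudes, train$steps)
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Rebuild a spike train from a per-step amplitude vector
#'
#' Inverse of [train_to_steps()] up to the superposition of same-step events:
#' each nonzero step becomes a single event carrying the summed amplitude.
#'
#' @param steps Numeric vector of length `n_steps`.
#' @param grid The [sim_grid()].
#' @return A [spike_train()].
#' @export
steps_to_train <- function(steps, grid) {
  stopifnot(inherits(grid, "sim_grid"), length(steps) == grid$n_steps)
  idx <- which(steps != 0)
  spike_train(idx * grid$dt, steps[idx], grid)
}

#' Write a spike train to a two-column CSV (time, amplitude)
#'
#' @param train A [spike_train()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_train_csv <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  utils::write.csv(
    data.frame(time = train$times, amplitude = train$amplitudes),
    path, row.names = FALSE)
  invisible(path)
}
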