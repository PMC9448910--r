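#' Discrete simulation grid
#'
#' All spike trains and membrane traces in lifmap live on a shared uniform
#' time grid. The grid is defined by the time step `dt` (the minimum time
#' unit, default 0.01 s) and the time window `t_window` (coding/simulation
#' duration). Grid step `s` corresponds to time `s * dt`, `s = 1..n_steps`.
#'
#' @param dt Time step in seconds. Must be positive.
#' @param t_window Time window in seconds. Must be at least `dt`.
#' @return An object of class `sim_grid` with fields `dt`, `t_window` and
#'   `n_steps = round(t_window / dt)`.
#' @examples
#' g <- sim_grid(dt = 0.01, t_window = 3)
#' g$n_steps # 300
#' @export
sim_grid <- function(dt = 0.01, t_window = 3) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  if (!is.numeric(t_window) || length(t_window) != 1L || !is.finite(t_window) ||
      t_window < dt)
    stop("`t_window` must be a single number >= dt", call. = FALSE)
  n_steps <- as.integer(round(t_window / dt))
  if (n_steps < 1L) stop("grid must contain at least one step", call. = FALSE)
  structure(list(dt = dt, t_window = t_window, n_steps = n_steps),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> dt = %g s, t_window = %g s, %d steps\n",
              x$dt, x$t_window, x$n_steps))
  invisible(x)
}

#' Snap event times to the grid
#'
#' Maps continuous times to the nearest grid step; ties (a time exactly
#' halfway between two steps) go to the earlier step, so spike counts are
#' reproducible bit-exactly. Steps are clamped to `[1, n_steps]`.
#'
#' @param times Numeric vector of times in `(0, t_window]`.
#' @param grid A [sim_grid()].
#' @return Integer vector of grid step indices.
#' @export
snap_to_grid <- function(times, grid) {
  stopifnot(inherits(grid, "sim_grid"))
  if (any(times <= 0 | times > grid$t_window + 1e-9))
    stop("event times must lie in (0, t_window]", call. = FALSE)
  s <- as.integer(ceiling(times / grid$dt - 0.5))
  pmin(pmax(s, 1L), grid$n_steps)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$dt, b$dt)) && isTRUE(all.equal(a$t_window, b$t_window))
}
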