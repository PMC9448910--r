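#' Grid of spike trains (spike tensor)
#'
#' A spike tensor holds one spike train per unit of a layer, all sharing
#' one [sim_grid()]. Internally the trains are stored as a per-step
#' amplitude matrix (`n_steps` rows, one column per unit); unit columns are
#' ordered column-major over `(H, W, C)` (H fastest, then W, then C), the
#' native R array order, which is also the flatten contract.
#'
#' @param steps Numeric matrix, `n_steps` x `prod(shape)`.
#' @param shape Integer vector: `N` for a flat layer or `c(H, W, C)`.
#' @param grid The shared [sim_grid()].
#' @return An object of class `spike_tensor`.
#' @export
spike_tensor <- function(steps, shape, grid) {
  stopifnot(inherits(grid, "sim_grid"))
  steps <- as.matrix(steps)
  shape <- as.integer(shape)
  if (nrow(steps) != grid$n_steps)
    stop("`steps` must have n_steps rows", call. = FALSE)
  if (ncol(steps) != prod(shape))
    stop("shape error: `steps` has ", ncol(steps), " columns but shape ",
         paste(shape, collapse = "x"), " implies ", prod(shape),
         call. = FALSE)
  structure(list(steps = steps, shape = shape, grid = grid),
            class = "spike_tensor")
}

#' @export
print.spike_tensor <- function(x, ...) {
  cat(sprintf("<spike_tensor> shape %s, %d steps, %d total spikes\n",
              paste(x$shape, collapse = "x"), nrow(x$steps),
              sum(x$steps != 0)))
  invisible(x)
}

#' Per-unit spike counts of a spike tensor
#' @param x A [spike_tensor()].
#' @return Numeric vector of event counts (nonzero steps) per unit.
#' @export
tensor_counts <- function(x) {
  stopifnot(inherits(x, "spike_tensor"))
  colSums(x$steps != 0)
}

#' Per-unit decoded frequencies of a spike tensor
#' @param x A [spike_tensor()].
#' @param T Coding time (defaults to the grid window).
#' @return Numeric vector in Hz.
#' @export
tensor_frequencies <- function(x, T = x$grid$t_window) {
  tensor_counts(x) / T
}

#' Extract one unit's spike train from a spike tensor
#' @param x A [spike_tensor()].
#' @param i Unit (column) index.
#' @return A [spike_train()].
#' @export
tensor_train <- function(x, i) {
  stopifnot(inherits(x, "spike_tensor"))
  steps_to_train(x$steps[, i], x$grid)
}

#' Encode a real tensor into a spike tensor
#'
#' Rate-encodes every element of `x` (values in `[0, 1]`, flattened
#' column-major) into a unit-amplitude periodic train.
#'
#' @param x Numeric vector or array with values in `[0, 1]`.
#' @param code A [rate_code()].
#' @return A [spike_tensor()] with shape `dim(x)` (or `length(x)`).
#' @export
encode_tensor <- function(x, code) {
  stopifnot(inherits(code, "rate_code"))
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  v <- as.numeric(x)
  S <- matrix(0, code$grid$n_steps, length(v))
  for (i in seq_along(v)) {
    tr <- encode_rate(v[i], code)
    if (length(tr$steps)) S[, i] <- train_to_steps(tr)
  }
  spike_tensor(S, shape, code$grid)
}

# ---- layer specifications ---------------------------------------------------

new_layer_spec <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "layer_spec")
}

#' @export
print.layer_spec <- function(x, ...) {
  extra <- switch(x$kind,
    dense = sprintf("%d -> %d", ncol(x$weights), nrow(x$weights)),
    conv2d = sprintf("%s filter, stride %d, padding %s",
                     paste(dim(x$weights), collapse = "x"), x$stride,
                     as.character(x$padding)),
    maxpool2d = sprintf("%s window, stride %d",
                        paste(x$window, collapse = "x"), x$stride),
    flatten = "")
  cat(sprintf("<layer_spec:%s> %s\n", x$kind, extra))
  invisible(x)
}

#' Dense (fully connected) layer specification
#'
#' @param weights `M x N` weight matrix (output units in rows).
#' @param bias Per-output bias (scalar recycled; must be `<= 0` for the LIF
#'   mapping).
#' @param slope ReLU activation slope.
#' @return A `layer_spec` of kind `"dense"`.
#' @export
layer_dense <- function(weights, bias = 0, slope = 1) {
  weights <- as.matrix(weights)
  new_layer_spec("dense", list(weights = weights,
                               bias = rep_len(bias, nrow(weights)),
                               slope = slope, lif = NULL))
}

#' 2-D convolution layer specification
#'
#' Cross-correlation orientation (deep-learning convention, no kernel
#' flip). Padding `"same"` (stride 1 keeps H and W) pads with zero spike
#' trains on the spiking side and zeros on the artificial side.
#'
#' @param weights Filter array `k_h x k_w x C_in x C_out`.
#' @param bias Per-output-channel bias (scalar recycled).
#' @param slope ReLU activation slope.
#' @param stride Positive integer stride.
#' @param padding `"same"` or a non-negative integer pad width.
#' @return A `layer_spec` of kind `"conv2d"`.
#' @export
layer_conv2d <- function(weights, bias = 0, slope = 1, stride = 1,
                         padding = "same") {
  weights <- as.array(weights)
  if (length(dim(weights)) != 4L)
    stop("conv2d weights must be a k_h x k_w x C_in x C_out array",
         call. = FALSE)
  if (stride < 1 || stride != round(stride))
    stop("`stride` must be a positive integer", call. = FALSE)
  if (!identical(padding, "same") &&
      (!is.numeric(padding) || padding < 0 || padding != round(padding)))
    stop("`padding` must be \"same\" or a non-negative integer",
         call. = FALSE)
  new_layer_spec("conv2d", list(weights = weights,
                                bias = rep_len(bias, dim(weights)[4L]),
                                slope = slope, stride = as.integer(stride),
                                padding = padding, lif = NULL))
}

#' Max-pooling layer specification
#'
#' @param window Pooling window `c(h, w)`.
#' @param stride Positive integer stride (default: window height).
#' @return A `layer_spec` of kind `"maxpool2d"`.
#' @export
layer_maxpool2d <- function(window = c(2, 2), stride = window[1]) {
  window <- as.integer(rep_len(window, 2L))
  new_layer_spec("maxpool2d", list(window = window,
                                   stride = as.integer(stride)))
}

#' Flatten layer specification
#'
#' Reshapes `(H, W, C)` to a flat vector in column-major order (H fastest,
#' then W, then C) — the order dense weights following a flatten must use.
#'
#' @return A `layer_spec` of kind `"flatten"`.
#' @export
layer_flatten <- function() new_layer_spec("flatten", list())

# padding width for a conv spec on a given input
conv_pad <- function(spec, in_shape) {
  if (identical(spec$padding, "same")) {
    (dim(spec$weights)[1L] - 1L) %/% 2L
  } else {
    as.integer(spec$padding)
  }
}

#' Output shape of a layer
#'
#' @param spec A `layer_spec`.
#' @param in_shape Input shape (`N` or `c(H, W, C)`).
#' @return Output shape; errors on inconsistent shapes.
#' @export
layer_output_shape <- function(spec, in_shape) {
  in_shape <- as.integer(in_shape)
  switch(spec$kind,
    dense = {
      if (prod(in_shape) != ncol(spec$weights))
        stop("shape error: dense layer expects ", ncol(spec$weights),
             " inputs, got ", prod(in_shape), call. = FALSE)
      nrow(spec$weights)
    },
    conv2d = {
      if (length(in_shape) != 3L)
        stop("shape error: conv2d needs an (H, W, C) input", call. = FALSE)
      kd <- dim(spec$weights)
      if (kd[3L] != in_shape[3L])
        stop("shape error: filter has ", kd[3L], " channels, input has ",
             in_shape[3L], call. = FALSE)
      p <- conv_pad(spec, in_shape)
      oh <- (in_shape[1L] + 2L * p - kd[1L]) %/% spec$stride + 1L
      ow <- (in_shape[2L] + 2L * p - kd[2L]) %/% spec$stride + 1L
      if (oh < 1L || ow < 1L)
        stop("shape error: filter larger than padded input", call. = FALSE)
      c(oh, ow, kd[4L])
    },
    maxpool2d = {
      if (length(in_shape) != 3L)
        stop("shape error: maxpool2d needs an (H, W, C) input", call. = FALSE)
      oh <- (in_shape[1L] - spec$window[1L]) %/% spec$stride + 1L
      ow <- (in_shape[2L] - spec$window[2L]) %/% spec$stride + 1L
      if (oh < 1L || ow < 1L)
        stop("shape error: pooling window does not fit input", call. = FALSE)
      c(oh, ow, in_shape[3L])
    },
    flatten = prod(in_shape),
    stop("unknown layer kind: ", spec$kind, call. = FALSE))
}

# Expand a conv2d spec into an explicit (out_units x in_units) weight
# matrix (cross-correlation, zero padding). Units are column-major over
# (H, W, C). Shared by the spiking and artificial sides, which makes the
# pre-threshold linearity of the two exactly identical.
conv_weight_matrix <- function(spec, in_shape) {
  in_shape <- as.integer(in_shape)
  out_shape <- layer_output_shape(spec, in_shape)
  H <- in_shape[1L]; W <- in_shape[2L]; C <- in_shape[3L]
  kd <- dim(spec$weights)
  p <- conv_pad(spec, in_shape)
  s <- spec$stride
  n_out <- prod(out_shape)
  Wm <- matrix(0, n_out, H * W * C)
  for (co in seq_len(out_shape[3L])) {
    for (ow in seq_len(out_shape[2L])) {
      for (oh in seq_len(out_shape[1L])) {
        o <- oh + (ow - 1L) * out_shape[1L] +
          (co - 1L) * out_shape[1L] * out_shape[2L]
        for (ci in seq_len(C)) {
          for (kw in seq_len(kd[2L])) {
            iw <- (ow - 1L) * s + kw - p
            if (iw < 1L || iw > W) next
            for (kh in seq_len(kd[1L])) {
              ih <- (oh - 1L) * s + kh - p
              if (ih < 1L || ih > H) next
              i <- ih + (iw - 1L) * H + (ci - 1L) * H * W
              Wm[o, i] <- Wm[o, i] + spec$weights[kh, kw, ci, co]
            }
          }
        }
      }
    }
  }
  list(W = Wm, out_shape = out_shape)
}

# member index list per pooling window, in (h-fastest, then w) order used
# for the first-occurrence tie-break; channels pooled independently
pool_windows <- function(spec, in_shape) {
  H <- in_shape[1L]; W <- in_shape[2L]; C <- in_shape[3L]
  out_shape <- layer_output_shape(spec, in_shape)
  s <- spec$stride
  wins <- vector("list", prod(out_shape))
  for (c0 in seq_len(C)) {
    for (ow in seq_len(out_shape[2L])) {
      for (oh in seq_len(out_shape[1L])) {
        o <- oh + (ow - 1L) * out_shape[1L] +
          (c0 - 1L) * out_shape[1L] * out_shape[2L]
        idx <- integer(0)
        for (dw in seq_len(spec$window[2L])) {
          for (dh in seq_len(spec$window[1L])) {
            ih <- (oh - 1L) * s + dh
            iw <- (ow - 1L) * s + dw
            idx <- c(idx, ih + (iw - 1L) * H + (c0 - 1L) * H * W)
          }
        }
        wins[[o]] <- idx
      }
    }
  }
  list(windows = wins, out_shape = out_shape)
}

# map a ReLU layer's per-neuron (weight row sum, bias, slope) onto per-
# neuron LIF parameters at threshold Vth; errors name the offending neuron
map_layer_lif <- function(row_sums, bias, slope, Vth, layer_label = "layer") {
  Cm <- 1 / (slope * Vth)
  gl <- numeric(length(row_sums))
  for (i in seq_along(row_sums)) {
    if (bias[i] > 0)
      stop("unsupported-bias error: ", layer_label, " neuron ", i,
           " has positive bias", call. = FALSE)
    if (bias[i] < 0) {
      if (row_sums[i] <= 0 || row_sums[i] >= Vth * Cm)
        stop("mapping-domain error: ", layer_label, " neuron ", i,
             ": sum(weights) must lie in (0, Vth*Cm) for a biased neuron",
             call. = FALSE)
      a <- row_sums[i] / (Vth * Cm)
      gl[i] <- bias[i] * Cm * log(1 - a) / row_sums[i]
    }
  }
  list(Cm = Cm, gl = gl, Vth = Vth)
}

# ---- spiking layers ---------------------------------------------------------

require_lif <- function(spec) {
  if (is.null(spec$lif))
    stop("layer has no LIF parameters; convert it first (see convert()) or ",
         "attach spec$lif = list(Cm, gl, Vth)", call. = FALSE)
  spec$lif
}

#' Spiking dense layer
#'
#' Each output unit receives the weighted superposition of all input trains
#' (weights in amplitudes) and integrates it with its own linear-reset LIF
#' parameters; outputs are re-emitted as unit-amplitude trains, so the next
#' layer's weights supply the amplitudes.
#'
#' @param input A flat [spike_tensor()] of `N` trains.
#' @param spec A dense `layer_spec` carrying LIF parameters in `spec$lif`
#'   (a list `Cm`, `gl` per unit, `Vth`), as attached by [convert()].
#' @return A [spike_tensor()] of `M` unit-amplitude trains.
#' @export
snn_dense <- function(input, spec) {
  stopifnot(inherits(input, "spike_tensor"), spec$kind == "dense")
  lif <- require_lif(spec)
  if (ncol(input$steps) != ncol(spec$weights))
    stop("shape error: dense layer expects ", ncol(spec$weights),
         " input trains, got ", ncol(input$steps), call. = FALSE)
  charge <- input$steps %*% t(spec$weights)
  res <- lif_engine(charge, lif$Cm, lif$gl, lif$Vth, input$grid$dt, "linear")
  spike_tensor(res$S + 0, nrow(spec$weights), input$grid)
}

#' Spiking 2-D convolution layer
#'
#' Every output location/channel receives the weighted superposition of its
#' receptive-field trains (weights = filter entries, cross-correlation
#' orientation); zero padding contributes empty trains. The superposed
#' train then drives a linear-reset LIF neuron.
#'
#' @param input A [spike_tensor()] with shape `(H, W, C)`.
#' @param spec A conv2d `layer_spec` with LIF parameters in `spec$lif`.
#' @return A [spike_tensor()] with shape `(H', W', C_out)`.
#' @export
snn_conv2d <- function(input, spec) {
  stopifnot(inherits(input, "spike_tensor"), spec$kind == "conv2d")
  lif <- require_lif(spec)
  cw <- conv_weight_matrix(spec, input$shape)
  charge <- input$steps %*% t(cw$W)
  gl <- rep(lif$gl, each = prod(cw$out_shape[1:2]))
  res <- lif_engine(charge, lif$Cm, gl, lif$Vth, input$grid$dt, "linear")
  spike_tensor(res$S + 0, cw$out_shape, input$grid)
}

#' Spiking max-pooling layer
#'
#' Per pooling window, each member train's event count over the window is
#' computed and the train with the largest count is forwarded *unchanged*
#' (timing preserved — the layer only selects). Ties break toward the first
#' member in window order (h fastest, then w).
#'
#' @param input A [spike_tensor()] with shape `(H, W, C)`.
#' @param spec A maxpool2d `layer_spec`.
#' @return A [spike_tensor()] of the pooled shape.
#' @export
snn_maxpool2d <- function(input, spec) {
  stopifnot(inherits(input, "spike_tensor"), spec$kind == "maxpool2d")
  pw <- pool_windows(spec, input$shape)
  counts <- colSums(input$steps != 0)
  sel <- vapply(pw$windows, function(idx) idx[which.max(counts[idx])], 0L)
  spike_tensor(input$steps[, sel, drop = FALSE], pw$out_shape, input$grid)
}

#' Spiking flatten layer
#'
#' Identity on the stored trains: unit columns are already in the flatten
#' (column-major) order.
#'
#' @param input A [spike_tensor()].
#' @return The same trains with a flat shape.
#' @export
snn_flatten <- function(input) {
  stopifnot(inherits(input, "spike_tensor"))
  spike_tensor(input$steps, prod(input$shape), input$grid)
}

#' Reference artificial (ReLU) forward pass through one layer
#'
#' The non-spiking counterpart of the spiking layers, used as the
#' equivalence reference: dense/conv compute `slope * max(0, W x + b)`,
#' max-pooling takes the windowed maximum, flatten reshapes column-major.
#'
#' @param x Numeric vector (dense/flat) or array `(H, W, C)`.
#' @param spec A `layer_spec`.
#' @return Numeric vector or array of the layer's output shape.
#' @export
ann_forward <- function(x, spec) {
  stopifnot(inherits(spec, "layer_spec"))
  in_shape <- if (is.null(dim(x))) length(x) else dim(x)
  switch(spec$kind,
    dense = {
      if (prod(in_shape) != ncol(spec$weights))
        stop("shape error: dense layer expects ", ncol(spec$weights),
             " inputs", call. = FALSE)
      as.numeric(spec$slope * pmax(0, spec$weights %*% as.numeric(x) +
                                     spec$bias))
    },
    conv2d = {
      cw <- conv_weight_matrix(spec, in_shape)
      b <- rep(spec$bias, each = prod(cw$out_shape[1:2]))
      y <- spec$slope * pmax(0, as.numeric(cw$W %*% as.numeric(x)) + b)
      array(y, dim = cw$out_shape)
    },
    maxpool2d = {
      pw <- pool_windows(spec, in_shape)
      v <- as.numeric(x)
      y <- vapply(pw$windows, function(idx) max(v[idx]), 0)
      array(y, dim = pw$out_shape)
    },
    flatten = as.numeric(x),
    stop("unknown layer kind: ", spec$kind, call. = FALSE))
}
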