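#' Layered network description
#'
#' An ordered list of [layer specs][layer_dense()] plus the input shape.
#' Construction validates that consecutive layer shapes chain correctly
#' and reports the offending layer otherwise.
#'
#' @param layers List of `layer_spec` objects.
#' @param input_shape Input shape: `N` or `c(H, W, C)`.
#' @return An object of class `network_spec` with a `shapes` field holding
#'   the per-layer output shapes.
#' @export
network_spec <- function(layers, input_shape) {
  if (!is.list(layers) || !length(layers) ||
      !all(vapply(layers, inherits, TRUE, "layer_spec")))
    stop("`layers` must be a non-empty list of layer_spec objects",
         call. = FALSE)
  input_shape <- as.integer(input_shape)
  shapes <- vector("list", length(layers))
  sh <- input_shape
  for (i in seq_along(layers)) {
    sh <- tryCatch(layer_output_shape(layers[[i]], sh),
                   error = function(e)
                     stop("validation error at layer ", i, " (",
                          layers[[i]]$kind, "): ", conditionMessage(e),
                          call. = FALSE))
    shapes[[i]] <- sh
  }
  structure(list(layers = layers, input_shape = input_shape,
                 shapes = shapes, version = "lifmap-net-1"),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> input %s, %d layers:\n",
              paste(x$input_shape, collapse = "x"), length(x$layers)))
  for (i in seq_along(x$layers))
    cat(sprintf("  %d. %-9s -> %s\n", i, x$layers[[i]]$kind,
                paste(x$shapes[[i]], collapse = "x")))
  invisible(x)
}

#' Save / load a network description (JSON)
#'
#' The on-disk format is a single JSON manifest: a version tag, the input
#' shape, and per layer its kind, parameters, and weight tensor (stored
#' flat alongside its dimensions, full precision, so a save/load round trip
#' reproduces all weights bit-exactly).
#'
#' @param spec A [network_spec()].
#' @param path File path.
#' @return `save_spec`: `path`, invisibly. `load_spec`: a [network_spec()].
#' @export
save_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  ser <- list(
    version = spec$version,
    input_shape = spec$input_shape,
    layers = lapply(spec$layers, function(l) {
      out <- list(kind = l$kind)
      if (l$kind %in% c("dense", "conv2d")) {
        out$weights <- as.numeric(l$weights)
        out$dim <- dim(l$weights)
        out$bias <- l$bias
        out$slope <- l$slope
      }
      if (l$kind == "conv2d") {
        out$stride <- l$stride
        out$padding <- l$padding
      }
      if (l$kind == "maxpool2d") {
        out$window <- l$window
        out$stride <- l$stride
      }
      out
    }))
  # digits = I(17) serialises doubles with 17 significant digits, enough
  # for a bit-exact round trip
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_spec
#' @export
load_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$version, "lifmap-net-1"))
    stop("format error: unknown version tag ",
         deparse(ser$version), call. = FALSE)
  layers <- lapply(seq_len(nrow_or_len(ser$layers)), function(i) {
    l <- layer_record(ser$layers, i)
    switch(l$kind,
      dense = layer_dense(matrix(l$weights, l$dim[1], l$dim[2]),
                          bias = l$bias, slope = l$slope),
      conv2d = layer_conv2d(array(l$weights, l$dim), bias = l$bias,
                            slope = l$slope, stride = l$stride,
                            padding = if (identical(l$padding, "same"))
                              "same" else as.numeric(l$padding)),
      maxpool2d = layer_maxpool2d(l$window, l$stride),
      flatten = layer_flatten(),
      stop("format error: unknown layer kind ", l$kind, call. = FALSE))
  })
  network_spec(layers, ser$input_shape)
}

# jsonlite may simplify the layer list to a data.frame; normalise access
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
layer_record <- function(x, i) {
  if (is.data.frame(x)) {
    rec <- lapply(x, function(col) if (is.list(col)) col[[i]] else col[i])
    rec$kind <- as.character(rec$kind)
    lapply(rec, function(v) if (is.list(v)) unlist(v) else v)
  } else {
    x[[i]]
  }
}

#' Convert a ReLU network into a spiking network
#'
#' Applies the [relu_to_lif()] parameter mapping to every dense and conv2d
#' layer, neuron by neuron: weights pass through unchanged, the layer slope
#' fixes `Cm = 1/(slope * v_th)` and each neuron's bias fixes its leak
#' conductance. Max-pooling and flatten layers pass through. The resulting
#' model records, per spiking layer, which network layer it came from.
#'
#' @param spec A valid [network_spec()]; every biased neuron must satisfy
#'   the mapping validity condition `0 < sum(weights) < v_th * Cm` (a
#'   violation reports the layer and neuron index).
#' @param cfg A [mapping_config()].
#' @param grid A [sim_grid()] for the simulation.
#' @param code A [rate_code()] for the input stage.
#' @return An object of class `snn_model`.
#' @export
convert <- function(spec, cfg = mapping_config(), grid = sim_grid(),
                    code = rate_code(grid = grid)) {
  stopifnot(inherits(spec, "network_spec"), inherits(cfg, "mapping_config"),
            inherits(grid, "sim_grid"), inherits(code, "rate_code"))
  layers <- spec$layers
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "dense") {
      l$lif <- map_layer_lif(rowSums(l$weights), l$bias, l$slope, cfg$v_th,
                             paste0("layer ", i, " (dense)"))
    } else if (l$kind == "conv2d") {
      ch_sums <- apply(l$weights, 4L, sum)
      l$lif <- map_layer_lif(ch_sums, l$bias, l$slope, cfg$v_th,
                             paste0("layer ", i, " (conv2d)"))
    }
    layers[[i]] <- l
  }
  structure(list(layers = layers, input_shape = spec$input_shape,
                 shapes = spec$shapes, grid = grid, code = code, cfg = cfg,
                 provenance = seq_along(layers), ann_spec = spec),
            class = "snn_model")
}

#' @export
print.snn_model <- function(x, ...) {
  cat(sprintf("<snn_model> input %s, %d layers, Vth = %g, f_max = %g Hz, T_w = %g s\n",
              paste(x$input_shape, collapse = "x"), length(x$layers),
              x$cfg$v_th, x$code$f_max, x$grid$t_window))
  invisible(x)
}

#' Spike-based inference through a converted network
#'
#' Rate-encodes the input, propagates the spike tensor through every
#' spiking layer, counts output spikes and returns the index of the output
#' unit with the largest count (ties toward the smallest index). When no
#' output unit fires at all, the label defaults to 1 and the `silent` flag
#' is set.
#'
#' @param model An [convert()]ed `snn_model`.
#' @param x Numeric vector/array in `[0, 1]` matching the input shape.
#' @param keep_layers Keep every intermediate [spike_tensor()]?
#' @return List with `label` (1-based), `counts`, `frequencies`, `silent`,
#'   and (if requested) `layers`.
#' @export
snn_infer <- function(model, x, keep_layers = FALSE) {
  stopifnot(inherits(model, "snn_model"))
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  if (!identical(as.integer(shape), model$input_shape))
    stop("shape error: input shape ", paste(shape, collapse = "x"),
         " does not match model input ",
         paste(model$input_shape, collapse = "x"), call. = FALSE)
  tensor <- encode_tensor(x, model$code)
  kept <- if (keep_layers) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    tensor <- switch(l$kind,
      dense = snn_dense(tensor, l),
      conv2d = snn_conv2d(tensor, l),
      maxpool2d = snn_maxpool2d(tensor, l),
      flatten = snn_flatten(tensor))
    if (keep_layers) kept[[i]] <- tensor
  }
  counts <- tensor_counts(tensor)
  silent <- all(counts == 0)
  if (silent)
    warning("all output units are silent; label defaults to 1",
            call. = FALSE)
  out <- list(label = which.max(counts), counts = counts,
              frequencies = counts / model$grid$t_window, silent = silent)
  if (keep_layers) out$layers <- kept
  out
}

#' Reference artificial forward pass and argmax readout
#'
#' Runs [ann_forward()] through every layer on the input frequencies
#' `x * f_max` and returns the argmax label (ties toward the smallest
#' index), mirroring the spike-count readout of [snn_infer()].
#'
#' @param spec A [network_spec()].
#' @param x Numeric vector/array in `[0, 1]` matching the input shape.
#' @param f_max Maximum coding frequency placing `x` on the frequency
#'   scale used by the spiking side (default 10 Hz).
#' @param keep_layers Keep every intermediate activation?
#' @return List with `label`, `activations` (output layer) and (if
#'   requested) `layers`.
#' @export
ann_infer <- function(spec, x, f_max = 10, keep_layers = FALSE) {
  stopifnot(inherits(spec, "network_spec"))
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  if (!identical(as.integer(shape), spec$input_shape))
    stop("shape error: input shape ", paste(shape, collapse = "x"),
         " does not match network input ",
         paste(spec$input_shape, collapse = "x"), call. = FALSE)
  act <- if (is.null(dim(x))) as.numeric(x) * f_max else x * f_max
  kept <- if (keep_layers) vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    act <- ann_forward(act, spec$layers[[i]])
    if (keep_layers) kept[[i]] <- act
  }
  act <- as.numeric(act)
  out <- list(label = which.max(act), activations = act)
  if (keep_layers) out$layers <- kept
  out
}
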