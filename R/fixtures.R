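# Seeded synthetic generators standing in for external datasets: random
# ReLU networks, synthetic images (Gaussian blobs, oriented bars) and a
# linearly separable two-class image dataset with a hand-constructed
# reference network. Everything is reproducible from the seed alone.

# run `expr` under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fixture generator configuration
#'
#' @param seed Integer seed; the same seed yields bit-identical fixtures.
#' @param arch Architecture descriptor: a list of layer descriptors, each a
#'   list with `kind` (`"dense"`, `"conv2d"`, `"maxpool2d"`, `"flatten"`)
#'   and its parameters (`units` for dense; `filters`, `kernel` for conv2d;
#'   `window` for maxpool2d).
#' @param input_shape Network input shape (`N` or `c(H, W, C)`).
#' @param weight_scale Per-neuron weight budget: each neuron's (or
#'   filter's) weights are rescaled so `sum(|w|)` is at most this value
#'   (default 0.8, keeping biased mappings inside the validity region
#'   `sum(w) < Vth * Cm` and spike rates well conditioned).
#' @param image_shape Shape of generated images.
#' @param n_classes Class count for the two-class dataset (must be 2).
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1,
                           arch = list(list(kind = "dense", units = 8),
                                       list(kind = "dense", units = 4)),
                           input_shape = 16,
                           weight_scale = 0.8,
                           image_shape = c(8, 8, 1),
                           n_classes = 2) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(weight_scale) || weight_scale <= 0)
    stop("`weight_scale` must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), arch = arch,
                 input_shape = as.integer(input_shape),
                 weight_scale = weight_scale,
                 image_shape = as.integer(image_shape),
                 n_classes = as.integer(n_classes)),
            class = "fixture_config")
}

#' Generate a random ReLU network
#'
#' Weights are drawn layer by layer in architecture order: for each dense
#' or conv2d layer, standard-normal weights (column-major draw order), then
#' one uniform scale factor per neuron/filter in `(0.5, 1]` of
#' `weight_scale`, applied so each neuron's `sum(|w|)` equals
#' `weight_scale * u`. Bias-free by default; with `with_bias = TRUE` the
#' weights are made non-negative (absolute values) so every neuron
#' satisfies the mapping validity condition, and each neuron receives a
#' negative bias drawn within the valid range.
#'
#' @param cfg A [fixture_config()].
#' @param with_bias Draw negative biases (default `FALSE`)?
#' @return A [network_spec()].
#' @export
gen_network <- function(cfg, with_bias = FALSE) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed, {
    layers <- list()
    sh <- cfg$input_shape
    for (d in cfg$arch) {
      l <- switch(d$kind,
        dense = {
          n_in <- prod(sh)
          W <- matrix(rnorm(d$units * n_in), d$units, n_in)
          if (with_bias) W <- abs(W)
          sc <- cfg$weight_scale * runif(d$units, 0.5, 1)
          W <- W * sc / rowSums(abs(W))
          b <- if (with_bias) -runif(d$units, 0.05, 0.3) * rowSums(W) else 0
          layer_dense(W, bias = b)
        },
        conv2d = {
          k <- rep_len(d$kernel, 2L)
          n_ch <- sh[3L]
          Wf <- array(rnorm(k[1] * k[2] * n_ch * d$filters),
                      dim = c(k[1], k[2], n_ch, d$filters))
          if (with_bias) Wf <- abs(Wf)
          sc <- cfg$weight_scale * runif(d$filters, 0.5, 1)
          for (f in seq_len(d$filters))
            Wf[, , , f] <- Wf[, , , f] * sc[f] / sum(abs(Wf[, , , f]))
          b <- if (with_bias)
            -runif(d$filters, 0.05, 0.3) * apply(Wf, 4L, sum) else 0
          layer_conv2d(Wf, bias = b)
        },
        maxpool2d = layer_maxpool2d(rep_len(d$window, 2L)),
        flatten = layer_flatten(),
        stop("config error: unknown layer kind ", d$kind, call. = FALSE))
      sh <- layer_output_shape(l, sh)
      layers <- c(layers, list(l))
    }
    network_spec(layers, cfg$input_shape)
  })
}

# a single H x W (x 1) image: Gaussian blob or oriented bar, values [0, 1]
render_blob <- function(H, W, center, sigma) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  img <- exp(-((rr - center[1])^2 + (cc - center[2])^2) / (2 * sigma^2))
  pmin(pmax(img, 0), 1)
}

render_bar <- function(H, W, angle, width) {
  rr <- matrix(seq_len(H) - (H + 1) / 2, H, W)
  cc <- matrix(seq_len(W) - (W + 1) / 2, H, W, byrow = TRUE)
  d <- rr * sin(angle) - cc * cos(angle) # signed distance to a centre line
  img <- exp(-d^2 / (2 * width^2))
  pmin(pmax(img, 0), 1)
}

#' Generate synthetic images
#'
#' Reproducible images in `[0, 1]`: alternating Gaussian blobs (random
#' centre and width) and oriented bars (random angle).
#'
#' @param cfg A [fixture_config()] (fields `seed`, `image_shape`).
#' @param n Number of images.
#' @return List of `n` arrays of shape `image_shape`; each carries
#'   attributes `kind` (`"blob"` or `"bar"`) and its generating parameters
#'   (`center`/`sigma` or `angle`/`width`).
#' @export
gen_images <- function(cfg, n = 10) {
  stopifnot(inherits(cfg, "fixture_config"))
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]; C <- cfg$image_shape[3]
  with_seed(cfg$seed + 1L, {
    lapply(seq_len(n), function(i) {
      if (i %% 2L == 1L) {
        center <- c(runif(1, 2, H - 1), runif(1, 2, W - 1))
        sigma <- runif(1, 0.8, 1.6)
        out <- array(rep(render_blob(H, W, center, sigma), C),
                     dim = c(H, W, C))
        attr(out, "kind") <- "blob"
        attr(out, "center") <- center
        attr(out, "sigma") <- sigma
      } else {
        angle <- runif(1, 0, pi)
        width <- runif(1, 0.6, 1.2)
        out <- array(rep(render_bar(H, W, angle, width), C),
                     dim = c(H, W, C))
        attr(out, "kind") <- "bar"
        attr(out, "angle") <- angle
        attr(out, "width") <- width
      }
      out
    })
  })
}

#' Intensity-weighted centroid of an image
#'
#' @param img An `(H, W)` matrix or `(H, W, 1)` array.
#' @return `c(row, col)` centroid.
#' @export
image_centroid <- function(img) {
  m <- if (length(dim(img)) == 3L) img[, , 1L] else img
  rr <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cc <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  c(sum(rr * m), sum(cc * m)) / sum(m)
}

#' Generate a separable two-class image dataset with a reference network
#'
#' Class 1 images carry a Gaussian blob in the left half of the image,
#' class 2 in the right half (balanced, shuffled). The returned reference
#' network is hand-constructed, not trained: a 3x3 averaging convolution
#' (same padding), 2x2 max-pooling, flatten, and a 2-unit dense readout
#' whose first unit sums the left half of the pooled map and second unit
#' the right half. Every neuron respects the `weight_scale` budget. By
#' construction the reference network classifies its own data essentially
#' perfectly, so spiking-vs-artificial label agreement can be measured
#' without any training.
#'
#' @param cfg A [fixture_config()] with `n_classes = 2`.
#' @param n Number of images.
#' @return List with `inputs` (list of `(H, W, 1)` arrays), `labels`
#'   (integer, 1 or 2) and `spec` (the reference [network_spec()]).
#' @export
gen_two_class_dataset <- function(cfg, n = 40) {
  stopifnot(inherits(cfg, "fixture_config"))
  if (cfg$n_classes != 2L)
    stop("the two-class generator requires n_classes = 2", call. = FALSE)
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  half <- W / 2
  with_seed(cfg$seed + 2L, {
    labels <- sample(rep(1:2, length.out = n))
    inputs <- lapply(labels, function(lab) {
      ctr_c <- if (lab == 1L) runif(1, 1.5, half - 0.5)
               else runif(1, half + 1.5, W - 0.5)
      img <- render_blob(H, W, c(runif(1, 2, H - 1), ctr_c),
                         runif(1, 0.8, 1.4))
      array(img, dim = c(H, W, 1L))
    })
    # averaging conv filter within the weight budget
    kf <- array(cfg$weight_scale / 9, dim = c(3, 3, 1, 1))
    pooled <- c(H %/% 2L, W %/% 2L)
    n_pool <- prod(pooled)
    Wd <- matrix(0, 2, n_pool)
    pw <- matrix(seq_len(pooled[2]), pooled[1], pooled[2], byrow = TRUE)
    left <- as.vector(pw) <= pooled[2] / 2
    w_unit <- cfg$weight_scale / (n_pool / 2)
    Wd[1, left] <- w_unit
    Wd[2, !left] <- w_unit
    spec <- network_spec(
      list(layer_conv2d(kf, padding = "same"),
           layer_maxpool2d(c(2, 2)),
           layer_flatten(),
           layer_dense(Wd)),
      c(H, W, 1L))
    list(inputs = inputs, labels = labels, spec = spec)
  })
}
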