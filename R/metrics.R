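#' Pearson correlation coefficient
#'
#' Product-moment correlation in the raw-sums form
#' `(n*Sxy - Sx*Sy) / sqrt((n*Sxx - Sx^2) * (n*Syy - Sy^2))`.
#' A zero-variance vector (e.g. a neuron silent on every input) makes the
#' coefficient undefined and raises an error; callers exclude such units
#' (see [correlation_matrices()], which does this automatically).
#'
#' @param x,y Numeric vectors of equal length `>= 2`.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  num <- n * sum(x * y) - sum(x) * sum(y)
  dx <- n * sum(x^2) - sum(x)^2
  dy <- n * sum(y^2) - sum(y)^2
  if (dx <= 0 || dy <= 0)
    stop("undefined-correlation error: zero variance", call. = FALSE)
  num / sqrt(dx * dy)
}

#' Cross-model correlation matrices
#'
#' Quantifies behavioural equivalence of a layer across a batch of inputs.
#' Rows of the two matrices index the inputs ("data"), columns the neurons.
#' \describe{
#'   \item{data dimension}{correlations between all pairs of data-indexed
#'     output vectors of the stacked `(ann; snn)` rows — a
#'     `(2 n_data) x (2 n_data)` matrix whose four quadrants are
#'     ann-vs-ann, ann-vs-snn, snn-vs-ann and snn-vs-snn.}
#'   \item{neuron dimension}{the same across neuron-indexed vectors,
#'     `(2 n_kept) x (2 n_kept)`; neurons with zero variance in either
#'     model are dropped first and reported in `excluded`.}
#' }
#'
#' @param snn_outputs `n_data x n_neuron` matrix of decoded SNN
#'   frequencies.
#' @param ann_outputs `n_data x n_neuron` matrix of matched ANN
#'   activations.
#' @return List with `data_dim`, `neuron_dim`, `excluded` (neuron indices
#'   dropped), and `cross_mean_rho` (mean diagonal of the cross quadrant
#'   of the data-dimension matrix, i.e. same-input cross-model
#'   correlation).
#' @export
correlation_matrices <- function(snn_outputs, ann_outputs) {
  snn_outputs <- as.matrix(snn_outputs)
  ann_outputs <- as.matrix(ann_outputs)
  if (!identical(dim(snn_outputs), dim(ann_outputs)))
    stop("shape error: output matrices must have identical dimensions",
         call. = FALSE)
  nd <- nrow(snn_outputs)
  safe_cor <- function(M) {
    # rows of M are observations' vectors; correlate all row pairs
    k <- nrow(M)
    out <- matrix(NA_real_, k, k)
    for (i in seq_len(k)) for (j in i:k) {
      r <- tryCatch(correlation(M[i, ], M[j, ]), error = function(e) NA_real_)
      out[i, j] <- out[j, i] <- r
    }
    out
  }
  data_dim <- safe_cor(rbind(ann_outputs, snn_outputs))
  var0 <- function(M) apply(M, 2L, function(v) isTRUE(all.equal(var(v), 0)) ||
                              var(v) == 0)
  excluded <- which(var0(snn_outputs) | var0(ann_outputs))
  keep <- setdiff(seq_len(ncol(snn_outputs)), excluded)
  neuron_dim <- if (length(keep) >= 1L)
    safe_cor(rbind(t(ann_outputs[, keep, drop = FALSE]),
                   t(snn_outputs[, keep, drop = FALSE])))
  else matrix(numeric(0), 0, 0)
  cross <- data_dim[cbind(seq_len(nd), nd + seq_len(nd))]
  list(data_dim = data_dim, neuron_dim = neuron_dim,
       excluded = excluded, cross_mean_rho = mean(cross, na.rm = TRUE))
}

#' Confusion matrix and agreement rate of two label vectors
#'
#' @param labels_a Reference labels (rows of the confusion matrix).
#' @param labels_b Predicted labels (columns).
#' @param n_classes Number of classes; labels must lie in `1..n_classes`.
#' @return List with `confusion` (`n_classes x n_classes` count matrix)
#'   and `rate` (`trace / total`).
#' @examples
#' agreement(c(1, 1, 2), c(1, 2, 2), 2)$rate # 2/3
#' @export
agreement <- function(labels_a, labels_b, n_classes) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  labels_a <- as.integer(labels_a)
  labels_b <- as.integer(labels_b)
  if (any(labels_a < 1L | labels_a > n_classes) ||
      any(labels_b < 1L | labels_b > n_classes))
    stop("out-of-range label", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(labels_a))
    cm[labels_a[i], labels_b[i]] <- cm[labels_a[i], labels_b[i]] + 1L
  list(confusion = cm, rate = agreement_rate(cm))
}

#' Agreement rate of a confusion matrix
#'
#' @param confusion A square count matrix (rows reference, columns
#'   predicted).
#' @return `trace / total`.
#' @examples
#' agreement_rate(matrix(c(200, 1, 0, 199), 2)) # 0.9975
#' @export
agreement_rate <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square", call. = FALSE)
  sum(diag(confusion)) / sum(confusion)
}

#' Write a confusion matrix to CSV
#' @param confusion A square count matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(confusion, path) {
  utils::write.csv(as.data.frame(confusion), path, row.names = FALSE)
  invisible(path)
}

#' Frequency-error report against the coding-time bound
#'
#' Compares decoded SNN output frequencies with their target (ANN)
#' frequencies and reports per-unit absolute errors in Hz against the
#' theoretical single-stage quantisation bound `1 / T`. Units exceeding
#' the bound are flagged, not fatal: through a cascade of layers the
#' per-layer bound compounds.
#'
#' @param f_snn Decoded frequencies in Hz.
#' @param f_ann Target frequencies in Hz (equal length).
#' @param T Coding time in seconds.
#' @param f_max Optional maximum coding frequency; when given, relative
#'   errors (fraction of `f_max`) are included.
#' @return An object of class `equivalence_report`: `abs_error`,
#'   `max_error`, `bound` (`1/T`), `exceeds_bound` (indices),
#'   `rel_error_pct` (if `f_max` given).
#' @export
frequency_error_report <- function(f_snn, f_ann, T, f_max = NULL) {
  if (length(f_snn) != length(f_ann))
    stop("frequency vectors must have equal length", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("`T` must be a single positive number", call. = FALSE)
  err <- abs(f_snn - f_ann)
  rep <- list(abs_error = err, max_error = if (length(err)) max(err) else 0,
              bound = 1 / T, exceeds_bound = which(err > 1 / T),
              T = T)
  if (!is.null(f_max)) rep$rel_error_pct <- 100 * err / f_max
  structure(rep, class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat(sprintf("<equivalence_report> %d units, max |f - f'| = %.4g Hz (bound 1/T = %.4g Hz), %d unit(s) above bound\n",
              length(x$abs_error), x$max_error, x$bound,
              length(x$exceeds_bound)))
  invisible(x)
}

#' Serialise an equivalence report to JSON
#' @param report An `equivalence_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_equivalence_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
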