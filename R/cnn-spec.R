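#' Build a 1D-CNN architecture specification
#'
#' The classifier family shares one structural rule set. Each of the
#' `n_blocks` basic blocks is convolution -> ReLU -> batch normalization,
#' followed by a max-pooling layer (size 2, stride 2). The first convolution
#' uses filters one second long (`round(fs * 1)` samples); every following
#' layer halves the filter length (floor) so the temporal resolution of the
#' filters stays constant relative to the halved feature maps. With 8 blocks
#' the pool after block 7 is dropped and block 8 reuses block 7's filter
#' length; pooling resumes after block 8. Convolutions are stride 1 with
#' length-preserving symmetric zero padding, so only pooling changes the
#' temporal length. The head is flatten -> dropout (20%) -> dense -> softmax.
#'
#' @param n_blocks number of convolutional blocks, 3 to 8.
#' @param input_len segment length in samples (e.g. 600 for 2 s, 1200 for 4 s
#'   at 300 Hz).
#' @param fs sampling frequency (Hz); sets the first filter length.
#' @param n_classes number of output classes.
#' @param filters_per_layer number of filters in every convolution (default 10).
#' @param pool_size max-pooling window and stride.
#' @param bn_epsilon batch-normalization epsilon.
#' @param dropout_rate dropout fraction between flatten and the dense layer.
#' @param conv_stride convolution stride (1 in this family).
#' @return an object of class `cnn_spec` with fields `filter_lengths`,
#'   `pool_after_block`, `stage_lengths` (temporal length after every block),
#'   `flatten_len` and `n_params` (closed-form trainable-parameter count).
#' @examples
#' spec <- cnn_spec(n_blocks = 3, input_len = 600, fs = 300, n_classes = 3)
#' spec$filter_lengths   # 300 150 75
#' spec$flatten_len      # 750
#' @export
cnn_spec <- function(n_blocks, input_len, fs, n_classes = 3,
                     filters_per_layer = 10, pool_size = 2,
                     bn_epsilon = 1e-3, dropout_rate = 0.2,
                     conv_stride = 1) {
  if (!is.numeric(n_blocks) || length(n_blocks) != 1 ||
      n_blocks < 3 || n_blocks > 8 || n_blocks != round(n_blocks))
    stop_cecg("`n_blocks` must be an integer in [3, 8]", "cecg_invalid_depth")
  n_blocks <- as.integer(n_blocks)
  stopifnot(input_len >= 2, fs > 0, n_classes >= 2, filters_per_layer >= 1,
            conv_stride == 1, pool_size == 2, bn_epsilon > 0,
            dropout_rate >= 0, dropout_rate < 1)

  filter_lengths <- integer(n_blocks)
  filter_lengths[1] <- round(fs * 1)
  for (r in 2:n_blocks) {
    filter_lengths[r] <- if (n_blocks == 8L && r == 8L) filter_lengths[7]
                         else max(1L, as.integer(floor(filter_lengths[r - 1] / 2)))
  }
  pool_after_block <- rep(TRUE, n_blocks)
  if (n_blocks == 8L) pool_after_block[7] <- FALSE

  stage_lengths <- integer(n_blocks)
  len <- as.integer(input_len)
  for (r in seq_len(n_blocks)) {
    if (pool_after_block[r]) len <- as.integer(floor(len / pool_size))
    if (len < 1)
      stop_cecg(sprintf("input_len %d collapses to length 0 at block %d",
                        input_len, r), "cecg_degenerate_architecture")
    stage_lengths[r] <- len
  }
  flatten_len <- filters_per_layer * len

  c_in <- c(1L, rep(filters_per_layer, n_blocks - 1))
  n_params <- sum(filter_lengths * c_in * filters_per_layer +  # conv weights
                  filters_per_layer +                          # conv biases
                  2L * filters_per_layer) +                    # BN gamma, beta
    flatten_len * n_classes + n_classes                        # dense head

  structure(list(
    n_blocks = n_blocks, input_len = as.integer(input_len), fs = fs,
    n_classes = as.integer(n_classes),
    filters_per_layer = as.integer(filters_per_layer),
    filter_lengths = filter_lengths, conv_stride = 1L,
    pool_after_block = pool_after_block, pool_size = as.integer(pool_size),
    bn_epsilon = bn_epsilon, dropout_rate = dropout_rate,
    activation = "relu", head = "flatten-dropout-dense-softmax",
    stage_lengths = stage_lengths, flatten_len = as.integer(flatten_len),
    n_params = as.integer(n_params)
  ), class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("1D-CNN spec: %d blocks, input %d samples (%g Hz), %d classes\n",
              x$n_blocks, x$input_len, x$fs, x$n_classes))
  cat(sprintf("  filters/layer %d, dropout %.0f%%, BN eps %g, %s activation\n",
              x$filters_per_layer, 100 * x$dropout_rate, x$bn_epsilon,
              x$activation))
  df <- data.frame(block = seq_len(x$n_blocks),
                   filter_len = x$filter_lengths,
                   pool = x$pool_after_block,
                   out_len = x$stage_lengths)
  print(df, row.names = FALSE)
  cat(sprintf("  flatten %d -> dense %d (%d trainable parameters)\n",
              x$flatten_len, x$n_classes, x$n_params))
  invisible(x)
}

#' Serialize / deserialize an architecture spec as JSON
#' @param spec a [cnn_spec()].
#' @param path optional file path; when omitted the JSON string is returned.
#' @return JSON string (or the path, invisibly, when `path` is given).
#' @export
cnn_spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "cnn_spec"))
  if (is.null(path))
    return(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cnn_spec_to_json
#' @param json JSON string or file path produced by [cnn_spec_to_json()].
#' @export
cnn_spec_from_json <- function(json) {
  x <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
       else jsonlite::fromJSON(json)
  cnn_spec(x$n_blocks, x$input_len, x$fs, x$n_classes, x$filters_per_layer,
           x$pool_size, x$bn_epsilon, x$dropout_rate, x$conv_stride)
}

#' Rectified linear unit
#'
#' `max(0, x)`, applied elementwise; idempotent and non-negative.
#' @param x numeric vector, matrix or array.
#' @return same shape as `x`.
#' @export
relu <- function(x) pmax(x, 0)

#' Batch normalization of a mini-batch
#'
#' `gamma * (x - mean) / sqrt(var + eps) + beta`, with the biased (population)
#' batch variance. For a matrix, statistics are computed per column (each
#' column one feature across the batch).
#'
#' @param batch numeric vector (batch of scalars) or matrix (rows = batch
#'   elements), batch size >= 2.
#' @param gamma,beta learned scale and shift (scalar or per-feature).
#' @param eps numerical stabilizer (>= 0; 0.001 in the classifier family).
#' @return normalized batch, same shape.
#' @export
batch_normalize <- function(batch, gamma = 1, beta = 0, eps = 1e-3) {
  if (eps < 0) stop_cecg("`eps` must be >= 0", "cecg_invalid_parameter")
  if (is.matrix(batch)) {
    if (nrow(batch) < 2)
      stop_cecg("batch size must be >= 2", "cecg_invalid_batch")
    mu <- colMeans(batch)
    v <- colMeans(sweep(batch, 2, mu)^2)
    xhat <- sweep(sweep(batch, 2, mu), 2, sqrt(v + eps), `/`)
    return(sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`))
  }
  if (length(batch) < 2)
    stop_cecg("batch size must be >= 2", "cecg_invalid_batch")
  mu <- mean(batch)
  v <- mean((batch - mu)^2)
  gamma * (batch - mu) / sqrt(v + eps) + beta
}

#' Numerically stable softmax
#'
#' `exp(x_i) / sum_j exp(x_j)` with max subtraction, so adding a constant to
#' all logits leaves the output unchanged and large logits cannot overflow.
#' For a matrix the softmax is taken along each row.
#'
#' @param x numeric vector of logits, or matrix (rows = samples).
#' @return probability vector/matrix summing to 1 per sample.
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    z <- exp(x - apply(x, 1, max))
    return(z / rowSums(z))
  }
  z <- exp(x - max(x))
  z / sum(z)
}
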