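#' Output width of a valid-padding 1-D convolution
#'
#' `floor((in_width - kernel_width) / stride) + 1`: the number of positions
#' at which a kernel of the given width fully overlaps the input when sliding
#' along the band axis.
#'
#' @param in_width,kernel_width,stride Positive integers with
#'   `in_width >= kernel_width`.
#' @return Integer output width.
#' @examples
#' conv_output_width(10, 2, 2)  # 5
#' @export
conv_output_width <- function(in_width, kernel_width, stride = 1L) {
  if (kernel_width < 1L || stride < 1L) stop_sfcnn("kernel width and stride must be >= 1")
  if (kernel_width > in_width) {
    stop_sfcnn("kernel width ", kernel_width, " exceeds input width ", in_width)
  }
  as.integer((in_width - kernel_width) %/% stride) + 1L
}

# Both architectures share one skeleton: a full-height spatial convolution
# (C1), a band-axis convolution across all C1 maps (C2), a flatten, a stack
# of fully connected ReLU layers, dropout feeding the output layer, and a
# 2-way softmax.
new_network_spec <- function(variant, n_channels, n_bands,
                             conv1_kernels, conv1_activation,
                             conv2_kernels, conv2_width, conv2_stride,
                             conv2_activation, hidden, dropout_rate) {
  conv1_width <- n_bands  # kernel width 1, stride 1
  conv2_out <- conv_output_width(conv1_width, conv2_width, conv2_stride)
  structure(
    list(variant = variant, input_shape = c(n_channels, n_bands),
         conv1_kernels = conv1_kernels, conv1_activation = conv1_activation,
         conv1_width = conv1_width,
         conv2_kernels = conv2_kernels, conv2_width = conv2_width,
         conv2_stride = conv2_stride, conv2_activation = conv2_activation,
         conv2_out_width = conv2_out,
         flatten_size = conv2_kernels * conv2_out,
         hidden = as.integer(hidden), hidden_activation = "relu",
         dropout_rate = dropout_rate, n_classes = 2L),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec:%s> input %dx%d\n", x$variant,
              x$input_shape[1], x$input_shape[2]))
  cat(sprintf("  C1: %d kernels [%d x 1], %s -> %d x (1 x %d)\n",
              x$conv1_kernels, x$input_shape[1], x$conv1_activation,
              x$conv1_kernels, x$conv1_width))
  cat(sprintf("  C2: %d kernels [width %d, stride %d], %s -> %d x (1 x %d)\n",
              x$conv2_kernels, x$conv2_width, x$conv2_stride,
              x$conv2_activation, x$conv2_kernels, x$conv2_out_width))
  cat(sprintf("  flatten %d -> FC %s -> dropout %.2f -> softmax %d\n",
              x$flatten_size, paste(x$hidden, collapse = "/"),
              x$dropout_rate, x$n_classes))
  invisible(x)
}

#' Base CNN architecture
#'
#' The standard two-convolution network: C1 applies 6 spatial filters, each a
#' full-height kernel (`n_channels x 1`) sliding along the band axis with
#' stride 1 and ReLU activation, so each C1 output value is a pure spatial
#' projection of one subband column. C2 applies 12 kernels of band-axis width
#' 2 (depth across all 6 C1 maps) with stride 2 and ReLU. The flattened
#' features feed a 50-unit ReLU layer, dropout at 0.5, and a 2-way softmax.
#'
#' @param n_channels,n_bands Input energy-map shape (electrodes x subbands).
#' @param dropout_rate Dropout probability before the output layer.
#' @return A `network_spec`.
#' @examples
#' build_base_network(21, 10)
#' @export
build_base_network <- function(n_channels, n_bands, dropout_rate = 0.5) {
  if (n_bands < 2L) stop_sfcnn("base network needs at least 2 subbands")
  new_network_spec("base", n_channels, n_bands,
                   conv1_kernels = 6L, conv1_activation = "relu",
                   conv2_kernels = 12L, conv2_width = 2L, conv2_stride = 2L,
                   conv2_activation = "relu", hidden = 50L,
                   dropout_rate = dropout_rate)
}

#' Cross-validation CNN architecture
#'
#' The deeper variant used with 10-fold cross-validation on 49-channel,
#' 6-band inputs: Conv_1 is 6 full-height (49 x 1) Elu kernels giving maps of
#' width 6; Conv_2 is 12 Elu kernels of band-axis width 3 and stride 2 giving
#' maps of width 2 (flatten 24); then fully connected ReLU layers of 50, 100
#' and 200 units, dropout, and a 2-way softmax.
#'
#' @param n_channels,n_bands Must be 49 and 6 for this variant.
#' @param dropout_rate Dropout probability before the output layer.
#' @return A `network_spec`.
#' @export
build_cv_network <- function(n_channels = 49L, n_bands = 6L, dropout_rate = 0.5) {
  if (n_channels != 49L || n_bands != 6L) {
    stop_sfcnn("cv variant is defined for input shape (49, 6); got (",
               n_channels, ", ", n_bands, ")")
  }
  new_network_spec("cv", 49L, 6L,
                   conv1_kernels = 6L, conv1_activation = "elu",
                   conv2_kernels = 12L, conv2_width = 3L, conv2_stride = 2L,
                   conv2_activation = "elu", hidden = c(50L, 100L, 200L),
                   dropout_rate = dropout_rate)
}

#' Rectified linear unit
#' @param v Numeric vector, matrix or array.
#' @return `pmax(v, 0)`, same shape.
#' @export
relu <- function(v) pmax(v, 0)

#' Exponential linear unit (alpha = 1)
#' @param v Numeric vector, matrix or array.
#' @return `v` where positive, `exp(v) - 1` elsewhere.
#' @export
elu <- function(v) ifelse(v > 0, v, exp(v) - 1)

activation_fn <- function(name) switch(name, relu = relu, elu = elu,
                                       stop_sfcnn("unknown activation ", name))

# derivative as a function of the pre-activation
activation_grad <- function(name) {
  switch(name,
         relu = function(pre) (pre > 0) * 1,
         elu = function(pre) ifelse(pre > 0, 1, exp(pre)),
         stop_sfcnn("unknown activation ", name))
}

#' Softmax over logits
#'
#' Computed with a max-logit shift for numerical stability; shift-invariant
#' and mathematically identical to `exp(z) / sum(exp(z))`.
#'
#' @param z Numeric vector of logits (or matrix with one column per sample).
#' @return Probabilities of the same shape, each column summing to 1.
#' @examples
#' softmax(c(log(2), 0))  # c(2/3, 1/3)
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    zs <- z - rep(apply(z, 2, max), each = nrow(z))
    e <- exp(zs)
    e / rep(colSums(e), each = nrow(z))
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Cross-entropy loss
#'
#' `H(p, q) = -sum(p * ln(q))` for a true distribution `p` and predicted
#' distribution `q`. Predicted probabilities are clipped at `eps` so a zero
#' probability on a supported class yields a large finite loss with a warning
#' rather than `Inf`.
#'
#' @param p True (typically one-hot) probability vector.
#' @param q Predicted probability vector.
#' @param eps Clipping floor for `q` (default 1e-12).
#' @return Scalar loss, >= 0.
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5))  # ln 2
#' @export
cross_entropy <- function(p, q, eps = 1e-12) {
  if (any(q < eps & p > 0)) {
    warning("predicted probability 0 on a supported class; clipped at ", eps)
  }
  -sum(p * log(pmax(q, eps)))
}

#' Dropout
#'
#' Training mode zeroes each entry independently with probability `rate`
#' (kept entries are passed through unscaled); inference mode deterministically
#' scales every entry by `1 - rate`, the test-time weight correction paired
#' with this training scheme.
#'
#' @param v Numeric vector or matrix of activations.
#' @param rate Dropout probability in `[0, 1)`.
#' @param mode `"train"` (stochastic mask) or `"infer"` (deterministic scale).
#' @return Same shape as `v`.
#' @export
dropout <- function(v, rate, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  if (rate < 0 || rate >= 1) stop_sfcnn("dropout rate must be in [0, 1)")
  if (rate == 0) return(v)
  if (mode == "infer") return(v * (1 - rate))
  mask <- runif(length(v)) >= rate
  v * mask
}

n_parameters <- function(spec) {
  C <- spec$input_shape[1]
  k1 <- spec$conv1_kernels; k2 <- spec$conv2_kernels
  widths <- c(spec$flatten_size, spec$hidden, spec$n_classes)
  k1 * C + k1 + k2 * k1 * spec$conv2_width + k2 +
    sum(widths[-length(widths)] * widths[-1]) + sum(widths[-1])
}

#' Initialize network parameters
#'
#' Weights are drawn i.i.d. from N(0, 0.1^2) using the seeded generator;
#' every bias is set to 0.1. The same `(spec, seed)` pair always yields the
#' identical parameter set.
#'
#' @param spec A `network_spec`.
#' @param seed Integer seed for the weight draw.
#' @return A `parameter_set`: weight matrices `W1`, `W2`, dense weights
#'   `Wd` (list, the last entry being the output layer) and matching biases.
#' @export
init_parameters <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(as.integer(seed))
  C <- spec$input_shape[1]
  k1 <- spec$conv1_kernels; k2 <- spec$conv2_kernels
  W1 <- matrix(rnorm(k1 * C, 0, 0.1), k1, C)
  b1 <- rep(0.1, k1)
  W2 <- matrix(rnorm(k2 * k1 * spec$conv2_width, 0, 0.1), k2,
               k1 * spec$conv2_width)
  b2 <- rep(0.1, k2)
  widths <- c(spec$flatten_size, spec$hidden, spec$n_classes)
  Wd <- list(); bd <- list()
  for (j in seq_len(length(widths) - 1L)) {
    Wd[[j]] <- matrix(rnorm(widths[j + 1] * widths[j], 0, 0.1),
                      widths[j + 1], widths[j])
    bd[[j]] <- rep(0.1, widths[j + 1])
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, Wd = Wd, bd = bd,
                 init_seed = as.integer(seed)),
            class = "parameter_set")
}

# Column indices mapping C1 activations into the im2col matrix for C2.
# A1 is k1 x (B * n); for offset d in 1:kw, output position t of sample i
# reads A1 column (i - 1) * B + (t - 1) * stride + d.
conv2_column_index <- function(spec, n) {
  B <- spec$conv1_width; Wo <- spec$conv2_out_width; s <- spec$conv2_stride
  lapply(seq_len(spec$conv2_width), function(d) {
    as.vector(outer((seq_len(Wo) - 1L) * s + d, (seq_len(n) - 1L) * B, `+`))
  })
}

# Forward pass over a batch. X: channels x bands x n array. Returns caches
# needed for backprop. dropout_mask: NULL (infer scaling) or a 0/1 matrix of
# shape (last hidden width) x n.
nn_forward_batch <- function(spec, params, X, dropout_mask = NULL) {
  C <- spec$input_shape[1]; B <- spec$input_shape[2]
  stopifnot(dim(X)[1] == C, dim(X)[2] == B)
  n <- dim(X)[3]
  act1 <- activation_fn(spec$conv1_activation)
  act2 <- activation_fn(spec$conv2_activation)
  Xall <- matrix(X, C, B * n)
  pre1 <- params$W1 %*% Xall + params$b1
  A1 <- act1(pre1)
  idx <- conv2_column_index(spec, n)
  k1 <- spec$conv1_kernels; kw <- spec$conv2_width
  Z <- matrix(0, k1 * kw, spec$conv2_out_width * n)
  for (d in seq_len(kw)) Z[(d - 1L) * k1 + seq_len(k1), ] <- A1[, idx[[d]]]
  pre2 <- params$W2 %*% Z + params$b2
  A2 <- act2(pre2)
  H <- matrix(A2, spec$flatten_size, n)
  preH <- list(); Hs <- list(H)
  nh <- length(spec$hidden)
  for (j in seq_len(nh)) {
    preH[[j]] <- params$Wd[[j]] %*% Hs[[j]] + params$bd[[j]]
    Hs[[j + 1]] <- relu(preH[[j]])
  }
  Hlast <- Hs[[nh + 1]]
  Hdrop <- if (is.null(dropout_mask)) Hlast * (1 - spec$dropout_rate)
           else Hlast * dropout_mask
  jout <- nh + 1L
  logits <- params$Wd[[jout]] %*% Hdrop + params$bd[[jout]]
  probs <- softmax(logits)
  list(Xall = Xall, pre1 = pre1, A1 = A1, Z = Z, idx = idx, pre2 = pre2,
       A2 = A2, Hs = Hs, preH = preH, Hdrop = Hdrop, mask = dropout_mask,
       logits = logits, probs = probs, n = n)
}

# Gradients of mean cross-entropy w.r.t. all parameters given a forward
# cache and one-hot targets Y (2 x n).
nn_backward_batch <- function(spec, params, cache, Y) {
  n <- cache$n
  nh <- length(spec$hidden); jout <- nh + 1L
  dLogits <- (cache$probs - Y) / n
  gWd <- vector("list", jout); gbd <- vector("list", jout)
  gWd[[jout]] <- dLogits %*% t(cache$Hdrop)
  gbd[[jout]] <- rowSums(dLogits)
  dHdrop <- t(params$Wd[[jout]]) %*% dLogits
  dH <- if (is.null(cache$mask)) dHdrop * (1 - spec$dropout_rate)
        else dHdrop * cache$mask
  for (j in rev(seq_len(nh))) {
    dPre <- dH * (cache$preH[[j]] > 0)
    gWd[[j]] <- dPre %*% t(cache$Hs[[j]])
    gbd[[j]] <- rowSums(dPre)
    dH <- t(params$Wd[[j]]) %*% dPre
  }
  dA2 <- matrix(dH, spec$conv2_kernels, spec$conv2_out_width * n)
  dPre2 <- dA2 * activation_grad(spec$conv2_activation)(cache$pre2)
  gW2 <- dPre2 %*% t(cache$Z)
  gb2 <- rowSums(dPre2)
  dZ <- t(params$W2) %*% dPre2
  k1 <- spec$conv1_kernels
  dA1 <- matrix(0, k1, ncol(cache$A1))
  for (d in seq_len(spec$conv2_width)) {
    rows <- (d - 1L) * k1 + seq_len(k1)
    cols <- cache$idx[[d]]
    dA1[, cols] <- dA1[, cols] + dZ[rows, , drop = FALSE]
  }
  dPre1 <- dA1 * activation_grad(spec$conv1_activation)(cache$pre1)
  list(W1 = dPre1 %*% t(cache$Xall), b1 = rowSums(dPre1),
       W2 = gW2, b2 = gb2, Wd = gWd, bd = gbd)
}

#' Forward pass: class probabilities for one energy map
#'
#' @param spec A `network_spec`.
#' @param params A matching `parameter_set`.
#' @param map An `energy_map` (or bare matrix) of shape `spec$input_shape`.
#' @param mode `"infer"` (deterministic; dropout becomes a `1 - rate` scale)
#'   or `"train"` (a fresh dropout mask is drawn from the current RNG state).
#' @return Length-2 probability vector (positive entries summing to 1).
#' @export
forward <- function(spec, params, map, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  vals <- if (inherits(map, "energy_map")) map$values else as.matrix(map)
  if (!all(dim(vals) == spec$input_shape)) {
    stop_sfcnn("input shape ", paste(dim(vals), collapse = "x"),
               " does not match network input ",
               paste(spec$input_shape, collapse = "x"))
  }
  X <- array(vals, dim = c(dim(vals), 1L))
  mask <- NULL
  if (mode == "train" && spec$dropout_rate > 0) {
    wlast <- spec$hidden[length(spec$hidden)]
    mask <- matrix((runif(wlast) >= spec$dropout_rate) * 1, wlast, 1L)
  } else if (mode == "train") {
    mask <- matrix(1, spec$hidden[length(spec$hidden)], 1L)
  }
  as.numeric(nn_forward_batch(spec, params, X, mask)$probs)
}

# Batch inference probabilities (2 x n) for a 3D array or list of maps.
predict_probs <- function(spec, params, maps) {
  X <- maps_to_array(maps)
  nn_forward_batch(spec, params, X, dropout_mask = NULL)$probs
}
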