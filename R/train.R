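#' Training configuration
#'
#' One gradient update per iteration is computed on the entire training set
#' (full-batch policy), minimizing mean cross-entropy. Model selection keeps
#' the parameters of the iteration with the highest validation accuracy
#' (earliest on ties).
#'
#' @param optimizer `"adam"` (default learning rate 1e-3) or `"adadelta"`
#'   (default learning rate 1.0, rho = 0.95).
#' @param learning_rate Step size; `NULL` uses the optimizer default.
#' @param max_iterations Number of full-batch updates (default 2000).
#' @param dropout_rate Dropout probability during training; `NULL` keeps the
#'   network spec's rate.
#' @param seed Master seed; init and dropout draw independent substreams.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "adadelta"),
                         learning_rate = NULL, max_iterations = 2000L,
                         dropout_rate = NULL, seed = 1L) {
  optimizer <- match.arg(optimizer)
  learning_rate <- learning_rate %||% switch(optimizer, adam = 1e-3, adadelta = 1.0)
  if (max_iterations < 1L) stop_sfcnn("max_iterations must be >= 1")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "train_config")
}

# ---- label plumbing -------------------------------------------------------

as_class_factor <- function(labels, levels = NULL) {
  f <- if (is.null(levels)) factor(labels) else factor(labels, levels = levels)
  if (nlevels(f) != 2L) {
    stop_sfcnn("labels must have exactly 2 classes, got ",
               paste(levels(f), collapse = ", "))
  }
  f
}

one_hot <- function(f) {
  Y <- matrix(0, 2L, length(f))
  Y[cbind(as.integer(f), seq_along(f))] <- 1
  Y
}

# ---- parameter arithmetic -------------------------------------------------

param_list <- function(p) {
  c(list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2),
    setNames(p$Wd, paste0("Wd", seq_along(p$Wd))),
    setNames(p$bd, paste0("bd", seq_along(p$bd))))
}

rebuild_params <- function(flat, template) {
  nd <- length(template$Wd)
  out <- template
  out$W1 <- flat$W1; out$b1 <- flat$b1; out$W2 <- flat$W2; out$b2 <- flat$b2
  out$Wd <- unname(flat[paste0("Wd", seq_len(nd))])
  out$bd <- unname(flat[paste0("bd", seq_len(nd))])
  out
}

grad_list <- function(g) {
  c(list(W1 = g$W1, b1 = g$b1, W2 = g$W2, b2 = g$b2),
    setNames(g$Wd, paste0("Wd", seq_along(g$Wd))),
    setNames(g$bd, paste0("bd", seq_along(g$bd))))
}

make_optimizer <- function(config, flat) {
  zeros <- lapply(flat, function(a) a * 0)
  if (config$optimizer == "adam") {
    state <- list(m = zeros, v = zeros, t = 0L)
    list(step = function(flat, grads, state) {
      state$t <- state$t + 1L
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      state$m <- Map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
      state$v <- Map(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
      c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
      flat <- Map(function(p, m, v) {
        p - config$learning_rate * (m / c1) / (sqrt(v / c2) + eps)
      }, flat, state$m, state$v)
      list(flat = flat, state = state)
    }, state = state)
  } else {
    state <- list(Eg = zeros, Edx = zeros)
    rho <- 0.95; eps <- 1e-6
    list(step = function(flat, grads, state) {
      state$Eg <- Map(function(e, g) rho * e + (1 - rho) * g^2, state$Eg, grads)
      dx <- Map(function(e, ed, g) -sqrt(ed + eps) / sqrt(e + eps) * g,
                state$Eg, state$Edx, grads)
      state$Edx <- Map(function(ed, d) rho * ed + (1 - rho) * d^2, state$Edx, dx)
      flat <- Map(function(p, d) p + config$learning_rate * d, flat, dx)
      list(flat = flat, state = state)
    }, state = state)
  }
}

batch_loss <- function(probs, Y, eps = 1e-12) {
  -mean(colSums(Y * log(pmax(probs, eps))))
}

batch_accuracy <- function(probs, f) {
  pred <- apply(probs, 2, which.max)  # ties -> lower class index
  mean(pred == as.integer(f))
}

# ---- training -------------------------------------------------------------

#' Train a network by full-batch backpropagation
#'
#' Runs `config$max_iterations` full-batch gradient updates of the mean
#' cross-entropy with the configured optimizer, recording training loss,
#' training accuracy and validation accuracy at every iteration, and returns
#' the parameters of the iteration with the highest validation accuracy
#' (earliest iteration on ties). Dropout is active only in the training-step
#' forward pass; all reported accuracies use deterministic inference.
#'
#' @param spec A `network_spec`.
#' @param x_train,x_val Lists of `energy_map`s (or channels x bands x n
#'   arrays) matching `spec$input_shape`.
#' @param y_train,y_val Class labels (2 classes; the factor level order
#'   defines the class index).
#' @param config A [train_config()].
#' @return A `cnn_fit` with elements `spec`, `params` (best), `final_params`,
#'   `history` (tibble: iteration, loss, train_accuracy, val_accuracy),
#'   `best_iteration`, `config`, `classes`, `n_updates`.
#' @export
train_network <- function(spec, x_train, y_train, x_val, y_val, config = train_config()) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "train_config"))
  Xtr <- maps_to_array(x_train); Xva <- maps_to_array(x_val)
  if (dim(Xtr)[3] == 0L || dim(Xva)[3] == 0L) {
    stop_sfcnn("training and validation sets must be non-empty")
  }
  ftr <- as_class_factor(y_train)
  fva <- as_class_factor(y_val, levels = levels(ftr))
  if (anyNA(fva)) stop_sfcnn("validation labels outside training classes")
  Y <- one_hot(ftr)
  n <- dim(Xtr)[3]

  rate <- config$dropout_rate %||% spec$dropout_rate
  spec_train <- spec; spec_train$dropout_rate <- rate
  params <- init_parameters(spec, substream_seed(config$seed, "init"))
  flat <- param_list(params)
  opt <- make_optimizer(config, flat)
  state <- opt$state
  wlast <- spec$hidden[length(spec$hidden)]

  iters <- config$max_iterations
  loss <- train_acc <- val_acc <- numeric(iters)
  best <- list(iter = 0L, acc = -Inf, flat = flat)
  n_updates <- 0L

  set.seed(substream_seed(config$seed, "dropout"))
  for (it in seq_len(iters)) {
    params_it <- rebuild_params(flat, params)
    mask <- if (rate > 0) {
      matrix((runif(wlast * n) >= rate) * 1, wlast, n)
    } else NULL
    cache <- nn_forward_batch(spec_train, params_it, Xtr, mask)
    loss[it] <- batch_loss(cache$probs, Y)
    if (!is.finite(loss[it])) {
      stop_sfcnn("non-finite training loss at iteration ", it)
    }
    grads <- grad_list(nn_backward_batch(spec_train, params_it, cache, Y))
    stepped <- opt$step(flat, grads, state)
    flat <- stepped$flat; state <- stepped$state
    n_updates <- n_updates + 1L

    params_now <- rebuild_params(flat, params)
    train_acc[it] <- batch_accuracy(predict_probs(spec, params_now, Xtr), ftr)
    va <- batch_accuracy(predict_probs(spec, params_now, Xva), fva)
    val_acc[it] <- va
    if (va > best$acc) best <- list(iter = it, acc = va, flat = flat)
  }

  structure(list(
    spec = spec,
    params = rebuild_params(best$flat, params),
    final_params = rebuild_params(flat, params),
    history = tibble::tibble(iteration = seq_len(iters), loss = loss,
                             train_accuracy = train_acc,
                             val_accuracy = val_acc),
    best_iteration = best$iter,
    config = config,
    classes = levels(ftr),
    channel_names = map_channel_names(x_train),
    n_updates = n_updates
  ), class = "cnn_fit")
}

map_channel_names <- function(maps) {
  if (is.list(maps) && length(maps) && inherits(maps[[1]], "energy_map")) {
    maps[[1]]$channel_names
  } else NULL
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("<cnn_fit:%s> %d iterations (%s), best validation accuracy %.3f at iteration %d\n",
              x$spec$variant, nrow(x$history), x$config$optimizer,
              max(x$history$val_accuracy), x$best_iteration))
  invisible(x)
}

#' Classification accuracy of a model on a labeled set
#'
#' Fraction of samples whose argmax predicted class (deterministic inference
#' forward pass; ties broken toward the lower class index) equals the label.
#'
#' @param object A `cnn_fit`, or a `network_spec` (then `params` is required).
#' @param maps List of `energy_map`s or a 3-D array.
#' @param labels True class labels.
#' @param params A `parameter_set` when `object` is a `network_spec`.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate <- function(object, maps, labels, params = NULL) {
  if (inherits(object, "cnn_fit")) {
    spec <- object$spec; params <- params %||% object$params
    f <- as_class_factor(labels, levels = object$classes)
  } else {
    spec <- object
    if (is.null(params)) stop_sfcnn("params required with a network_spec")
    f <- as_class_factor(labels)
  }
  X <- maps_to_array(maps)
  if (dim(X)[3] == 0L) stop_sfcnn("empty evaluation set")
  batch_accuracy(predict_probs(spec, params, X), f)
}

#' Predicted classes for a fitted network
#'
#' @param object A `cnn_fit`.
#' @param maps List of `energy_map`s or a 3-D array.
#' @param ... Unused.
#' @return Tibble with predicted class, and the two class probabilities.
#' @export
predict.cnn_fit <- function(object, maps, ...) {
  probs <- predict_probs(object$spec, object$params, maps)
  tibble::tibble(
    .pred_class = object$classes[apply(probs, 2, which.max)],
    .prob_1 = probs[1, ], .prob_2 = probs[2, ]
  )
}

#' Extract learned spatial filters from the first convolution layer
#'
#' The first layer's kernels span the full electrode axis, so each kernel is
#' a spatial filter: a weight per channel describing how strongly that
#' electrode drives the feature. Returned tidy, one row per
#' (filter, channel).
#'
#' @param object A `cnn_fit`, or a `network_spec` with `params` supplied.
#' @param params A `parameter_set` when `object` is a `network_spec`.
#' @param channel_names Optional electrode labels; defaults to those recorded
#'   at fit time, else `ch01, ...`.
#' @return Tibble with columns `filter`, `channel`, `channel_name`, `weight`.
#' @export
extract_spatial_filters <- function(object, params = NULL, channel_names = NULL) {
  if (inherits(object, "cnn_fit")) {
    spec <- object$spec; params <- params %||% object$params
    channel_names <- channel_names %||% object$channel_names
  } else {
    spec <- object
    if (is.null(params)) stop_sfcnn("params required with a network_spec")
  }
  stopifnot(inherits(spec, "network_spec"))
  C <- spec$input_shape[1]
  if (ncol(params$W1) != C) {
    stop_sfcnn("first layer is not a full-height spatial convolution")
  }
  channel_names <- channel_names %||% sprintf("ch%02d", seq_len(C))
  k1 <- spec$conv1_kernels
  tibble::tibble(
    filter = rep(seq_len(k1), each = C),
    channel = rep(seq_len(C), times = k1),
    channel_name = rep(channel_names, times = k1),
    weight = as.numeric(t(params$W1))
  )
}

# ---- broom-style methods --------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fit
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return The per-iteration history tibble.
#' @exportS3Method
tidy.cnn_fit <- function(x, ...) x$history

#' One-row summary of a fit
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return Tibble with iteration count, best iteration, best validation
#'   accuracy, final training loss/accuracy, and parameter count.
#' @exportS3Method
glance.cnn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    iterations = nrow(h),
    best_iteration = x$best_iteration,
    best_val_accuracy = max(h$val_accuracy),
    final_loss = h$loss[nrow(h)],
    final_train_accuracy = h$train_accuracy[nrow(h)],
    n_parameters = n_parameters(x$spec),
    optimizer = x$config$optimizer
  )
}
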