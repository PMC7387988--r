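# Independent brute-force implementation of the network forward pass:
# explicit nested loops over kernels, positions and neurons, no shared code
# with the package's vectorized path beyond the layer definitions.

oracle_activation <- function(name) {
  switch(name,
         relu = function(x) max(0, x),
         elu = function(x) if (x > 0) x else exp(x) - 1)
}

oracle_forward <- function(spec, params, M) {
  C <- spec$input_shape[1]; B <- spec$input_shape[2]
  k1 <- spec$conv1_kernels; k2 <- spec$conv2_kernels
  kw <- spec$conv2_width; s <- spec$conv2_stride
  a1fn <- oracle_activation(spec$conv1_activation)
  a2fn <- oracle_activation(spec$conv2_activation)

  a1 <- matrix(0, k1, B)
  for (k in seq_len(k1)) {
    for (j in seq_len(B)) {
      acc <- params$b1[k]
      for (c in seq_len(C)) acc <- acc + params$W1[k, c] * M[c, j]
      a1[k, j] <- a1fn(acc)
    }
  }
  Wo <- (B - kw) %/% s + 1L
  a2 <- matrix(0, k2, Wo)
  for (m in seq_len(k2)) {
    for (t in seq_len(Wo)) {
      acc <- params$b2[m]
      for (d in seq_len(kw)) {
        for (k in seq_len(k1)) {
          acc <- acc + params$W2[m, (d - 1) * k1 + k] * a1[k, (t - 1) * s + d]
        }
      }
      a2[m, t] <- a2fn(acc)
    }
  }
  h <- numeric(k2 * Wo)
  for (t in seq_len(Wo)) {
    for (m in seq_len(k2)) h[(t - 1) * k2 + m] <- a2[m, t]
  }
  for (j in seq_along(spec$hidden)) {
    W <- params$Wd[[j]]; b <- params$bd[[j]]
    hn <- numeric(nrow(W))
    for (i in seq_len(nrow(W))) {
      acc <- b[i]
      for (q in seq_len(ncol(W))) acc <- acc + W[i, q] * h[q]
      hn[i] <- max(0, acc)
    }
    h <- hn
  }
  h <- h * (1 - spec$dropout_rate)  # inference-time dropout correction
  jout <- length(spec$hidden) + 1L
  W <- params$Wd[[jout]]; b <- params$bd[[jout]]
  z <- numeric(2)
  for (i in 1:2) {
    acc <- b[i]
    for (q in seq_len(ncol(W))) acc <- acc + W[i, q] * h[q]
    z[i] <- acc
  }
  exp(z) / sum(exp(z))
}

# Mean cross-entropy of the deterministic (dropout-free) network on a batch,
# as a function of a flat parameter list; used for finite-difference checks.
oracle_batch_loss <- function(spec, flat, X, Y) {
  spec0 <- spec; spec0$dropout_rate <- 0
  params <- sfcnn:::rebuild_params(flat, init_parameters(spec, 1))
  cache <- sfcnn:::nn_forward_batch(spec0, params, X, NULL)
  sfcnn:::batch_loss(cache$probs, Y)
}

numeric_gradient <- function(fn, flat, h = 1e-5) {
  lapply(seq_along(flat), function(i) {
    g <- flat[[i]] * 0
    for (j in seq_along(flat[[i]])) {
      up <- flat; up[[i]][j] <- up[[i]][j] + h
      dn <- flat; dn[[i]][j] <- dn[[i]][j] - h
      g[j] <- (fn(up) - fn(dn)) / (2 * h)
    }
    g
  })
}
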