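## Minimal feed-forward network engine used by the autoencoders: dense and
## 1-D convolutional layers with ReLU, trained by Adam on mean squared error.
## Sequences are stored time-major with channels fastest, i.e. a length-L
## sequence with C channels occupies L*C columns as (t1c1..t1cC, t2c1..,...);
## with L = 12 months and C = 16 indices this is exactly the month-major
## composite layout, so no reshaping is needed at the network boundary.

nn_dense <- function(fan_in, fan_out, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  sdw <- if (activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
  list(type = "dense", activation = activation,
       W = matrix(rnorm(fan_in * fan_out, sd = sdw), fan_in, fan_out),
       b = numeric(fan_out))
}

## 1-D convolution over the time axis. kernel k, stride s, symmetric zero
## padding p. weights: (k*c_in) x c_out, window columns time-major.
nn_conv1d <- function(L_in, c_in, c_out, kernel = 3L, stride = 1L, pad = 1L,
                      activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  fan_in <- kernel * c_in
  sdw <- if (activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
  L_out <- (L_in + 2L * pad - kernel) %/% stride + 1L
  list(type = "conv1d", activation = activation,
       L_in = L_in, c_in = c_in, c_out = c_out, L_out = L_out,
       kernel = kernel, stride = stride, pad = pad,
       W = matrix(rnorm(fan_in * c_out, sd = sdw), fan_in, c_out),
       b = numeric(c_out))
}

## nearest-neighbour upsampling of the time axis by an integer factor
nn_upsample <- function(L_in, c_in, factor = 2L) {
  list(type = "upsample", L_in = L_in, c_in = c_in, factor = factor,
       L_out = L_in * factor)
}

apply_act <- function(z, activation) {
  if (activation == "relu") z * (z > 0) else z
}

conv_window_cols <- function(layer) {
  ## list over output positions of the padded-input column indices
  lapply(seq_len(layer$L_out), function(t) {
    wt <- (t - 1L) * layer$stride + seq_len(layer$kernel)   # padded time steps
    as.vector(outer(seq_len(layer$c_in), (wt - 1L) * layer$c_in, `+`))
  })
}

layer_forward <- function(layer, X) {
  switch(layer$type,
    dense = {
      Z <- sweep(X %*% layer$W, 2, layer$b, `+`)
      list(out = apply_act(Z, layer$activation), cache = list(X = X, Z = Z))
    },
    conv1d = {
      n <- nrow(X)
      Lp <- layer$L_in + 2L * layer$pad
      Xp <- matrix(0, n, Lp * layer$c_in)
      Xp[, layer$pad * layer$c_in + seq_len(layer$L_in * layer$c_in)] <- X
      wins <- conv_window_cols(layer)
      Z <- matrix(0, n, layer$L_out * layer$c_out)
      for (t in seq_len(layer$L_out)) {
        Z[, (t - 1L) * layer$c_out + seq_len(layer$c_out)] <-
          sweep(Xp[, wins[[t]], drop = FALSE] %*% layer$W, 2, layer$b, `+`)
      }
      list(out = apply_act(Z, layer$activation),
           cache = list(Xp = Xp, Z = Z, wins = wins))
    },
    upsample = {
      cols <- rep(seq_len(layer$L_in), each = layer$factor)
      idx <- as.vector(outer(seq_len(layer$c_in), (cols - 1L) * layer$c_in, `+`))
      list(out = X[, idx, drop = FALSE], cache = NULL)
    })
}

layer_backward <- function(layer, cache, dOut) {
  switch(layer$type,
    dense = {
      dZ <- if (layer$activation == "relu") dOut * (cache$Z > 0) else dOut
      list(dX = dZ %*% t(layer$W),
           grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ)))
    },
    conv1d = {
      dZ <- if (layer$activation == "relu") dOut * (cache$Z > 0) else dOut
      dW <- matrix(0, nrow(layer$W), ncol(layer$W))
      db <- numeric(layer$c_out)
      dXp <- matrix(0, nrow(dZ), ncol(cache$Xp))
      for (t in seq_len(layer$L_out)) {
        ct <- (t - 1L) * layer$c_out + seq_len(layer$c_out)
        dZt <- dZ[, ct, drop = FALSE]
        w <- cache$wins[[t]]
        dW <- dW + crossprod(cache$Xp[, w, drop = FALSE], dZt)
        db <- db + colSums(dZt)
        dXp[, w] <- dXp[, w] + dZt %*% t(layer$W)
      }
      list(dX = dXp[, layer$pad * layer$c_in +
                      seq_len(layer$L_in * layer$c_in), drop = FALSE],
           grads = list(W = dW, b = db))
    },
    upsample = {
      n <- nrow(dOut)
      dX <- matrix(0, n, layer$L_in * layer$c_in)
      for (f in seq_len(layer$factor)) {
        cols <- seq(f, by = layer$factor, length.out = layer$L_in)
        idx <- as.vector(outer(seq_len(layer$c_in), (cols - 1L) * layer$c_in, `+`))
        dX <- dX + dOut[, idx, drop = FALSE]
      }
      list(dX = dX, grads = NULL)
    })
}

net_forward <- function(net, X, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net)) else NULL
  for (i in seq_along(net)) {
    fw <- layer_forward(net[[i]], X)
    X <- fw$out
    if (keep_cache) caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches)
}

net_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    bw <- layer_backward(net[[i]], caches[[i]], dOut)
    grads[i] <- list(bw$grads)   # list-assign: NULL grads must not drop slots
    dOut <- bw$dX
  }
  grads
}

adam_init <- function(net) {
  lapply(net, function(l) {
    if (is.null(l$W)) NULL else
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(net, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net[[i]]$W <- net[[i]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net[[i]]$b <- net[[i]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}
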