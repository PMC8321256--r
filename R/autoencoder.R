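## Self-supervised compression of the 192-feature annual vegetation-index
## vectors.  Two architectures: a dense autoencoder (AE) and a 1-D
## convolutional autoencoder (CAE) that reads the vector as a 12-month
## sequence with 16 index channels.  Both are trained to reconstruct their
## z-scored input through a k-dimensional bottleneck (k in {3, 5, 10} by
## convention, any k < 192 accepted).

#' Fit per-feature standardization parameters
#'
#' Computes per-feature mean and standard deviation.  Features with (near)
#' zero variance cannot be z-scored; they are dropped from the model input
#' and reinserted as constants when decoding.
#'
#' @param X numeric matrix (pixels x features), no missing values.
#' @return list with `center`, `scale` (for kept features), `kept` (column
#'   indices), `const` (values of dropped columns) and `d` (input width).
#' @export
feature_scaler <- function(X) {
  stopifnot(is.matrix(X), !anyNA(X))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  kept <- which(scl > 1e-12)
  if (length(kept) < ncol(X))
    warning(sprintf("%d zero-variance feature(s) dropped; reinserted as constants at decode",
                    ncol(X) - length(kept)))
  list(center = ctr[kept], scale = scl[kept], kept = kept,
       const = ctr[setdiff(seq_len(ncol(X)), kept)], d = ncol(X))
}

#' @rdname feature_scaler
#' @param scaler a scaler from [feature_scaler()].
#' @export
apply_scaler <- function(scaler, X) {
  Xs <- X[, scaler$kept, drop = FALSE]
  sweep(sweep(Xs, 2, scaler$center, `-`), 2, scaler$scale, `/`)
}

#' @rdname feature_scaler
#' @param Xs standardized matrix over kept features.
#' @export
invert_scaler <- function(scaler, Xs) {
  out <- matrix(0, nrow(Xs), scaler$d)
  out[, scaler$kept] <- sweep(sweep(Xs, 2, scaler$scale, `*`), 2,
                              scaler$center, `+`)
  dropped <- setdiff(seq_len(scaler$d), scaler$kept)
  if (length(dropped))
    out[, dropped] <- matrix(scaler$const, nrow(Xs), length(dropped),
                             byrow = TRUE)
  out
}

## Architecture builders return list(net, n_enc): the first n_enc layers form
## the encoder (bottleneck output), the rest the decoder.
build_ae <- function(d_in, k) {
  list(net = list(nn_dense(d_in, 128, "relu"),
                  nn_dense(128, 64, "relu"),
                  nn_dense(64, k, "linear"),
                  nn_dense(k, 64, "relu"),
                  nn_dense(64, 128, "relu"),
                  nn_dense(128, d_in, "linear")),
       n_enc = 3L)
}

build_cae <- function(k) {
  ## encoder: 12x16 -> conv32 s2 -> 6x32 -> conv64 s2 -> 3x64 -> conv64 s1
  ## -> 3x64 -> dense 192 -> k; decoder mirrored with x2 upsampling
  list(net = list(nn_conv1d(12L, 16L, 32L, stride = 2L, activation = "relu"),
                  nn_conv1d(6L, 32L, 64L, stride = 2L, activation = "relu"),
                  nn_conv1d(3L, 64L, 64L, stride = 1L, activation = "relu"),
                  nn_dense(192L, k, "linear"),
                  nn_dense(k, 192L, "relu"),
                  nn_conv1d(3L, 64L, 64L, stride = 1L, activation = "relu"),
                  nn_upsample(3L, 64L),
                  nn_conv1d(6L, 64L, 32L, stride = 1L, activation = "relu"),
                  nn_upsample(6L, 32L),
                  nn_conv1d(12L, 32L, 16L, stride = 1L,
                            activation = "linear")),
       n_enc = 4L)
}

#' Fit an autoencoder to a feature matrix
#'
#' Standardizes `X` per feature, splits pixels at random into a training part
#' (`1 - val_fraction`, default 95%) and a validation part (5%), and trains
#' the chosen architecture by Adam to minimize mean squared reconstruction
#' error, with early stopping on the validation loss.  The run is fully
#' reproducible from `seed`.
#'
#' @param X numeric matrix, pixels x features (no missing values; use
#'   [fill_gaps()] upstream).  The CAE requires 192 columns (12 months x 16
#'   indices, month-major).
#' @param kind `"ae"` (dense) or `"cae"` (1-D convolutional over months).
#' @param k latent dimension; must be `< ncol(X)`.  The reference choices
#'   are 3, 5 and 10.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); the best-validation weights are restored.
#' @param val_fraction held-out fraction of pixels.
#' @param seed RNG seed governing initialization, split and shuffling.
#' @param verbose print per-epoch losses.
#' @return an object of class `encoder_model`: architecture, weights, scaler,
#'   training `history` (per-epoch train/validation MSE) and configuration.
#' @export
fit_autoencoder <- function(X, kind = c("ae", "cae"), k = 3L, epochs = 200L,
                            batch_size = 256L, lr = 1e-3, patience = 20L,
                            val_fraction = 0.05, seed = 42L, verbose = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(X), nrow(X) >= 100)
  if (k >= ncol(X))
    stop(sprintf("latent dimension k = %d must be smaller than the input width %d",
                 k, ncol(X)))
  if (kind == "cae" && ncol(X) != 192L)
    stop("the convolutional autoencoder requires 192 input features (12 months x 16 indices)")
  set.seed(seed)
  scaler <- feature_scaler(X)

  if (length(scaler$kept) == 0L) {
    ## fully constant input: nothing to learn, reconstruction is exact
    model <- structure(list(kind = kind, k = as.integer(k), net = NULL,
                            n_enc = 0L, scaler = scaler,
                            history = data.frame(epoch = 1L, train_loss = 0,
                                                 val_loss = 0),
                            seed = seed,
                            config = list(epochs = epochs,
                                          batch_size = batch_size, lr = lr,
                                          patience = patience,
                                          val_fraction = val_fraction)),
                       class = "encoder_model")
    return(model)
  }
  Xs <- apply_scaler(scaler, X)
  if (kind == "cae" && length(scaler$kept) != 192L)
    stop("CAE input has zero-variance features; the convolutional layout needs all 192")

  n <- nrow(Xs)
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr <- Xs[-val_idx, , drop = FALSE]
  va <- Xs[val_idx, , drop = FALSE]

  arch <- if (kind == "ae") build_ae(ncol(tr), k) else build_cae(k)
  net <- arch$net
  state <- adam_init(net)
  best <- list(loss = Inf, net = net, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(tr))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, nrow(tr), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, nrow(tr))]
      Xb <- tr[bi, , drop = FALSE]
      fw <- net_forward(net, Xb, keep_cache = TRUE)
      resid <- fw$out - Xb
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d; lower the learning rate", ep))
      grads <- net_backward(net, fw$caches, 2 * resid / length(resid))
      step <- step + 1L
      upd <- adam_step(net, grads, state, step, lr = lr)
      net <- upd$net
      state <- upd$state
      ep_loss <- ep_loss + loss * nrow(Xb)
      nb <- nb + nrow(Xb)
    }
    val_loss <- mean((net_forward(net, va)$out - va)^2)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, ep_loss / nb,
                      val_loss))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, net = net, epoch = ep)
    } else if (ep - best$epoch >= patience) break
  }
  structure(list(kind = kind, k = as.integer(k), net = best$net,
                 n_enc = arch$n_enc, scaler = scaler, history = hist,
                 val_idx = val_idx, seed = seed,
                 config = list(epochs = epochs, batch_size = batch_size,
                               lr = lr, patience = patience,
                               val_fraction = val_fraction)),
            class = "encoder_model")
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("<encoder_model> %s, k = %d, %d epoch(s) trained, final val MSE %.5g\n",
              toupper(x$kind), x$k, nrow(x$history),
              x$history$val_loss[nrow(x$history)]))
  invisible(x)
}

#' Encode a feature matrix to latent features
#'
#' Deterministic inference: standardizes `X` with the model's stored
#' parameters and runs the encoder half of the network.
#'
#' @param model an `encoder_model`.
#' @param X matrix with the same width the model was fitted on.
#' @return `nrow(X) x k` latent matrix (columns `L1..Lk`).
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "encoder_model"), is.matrix(X))
  if (ncol(X) != model$scaler$d)
    stop(sprintf("X has %d columns; model expects %d", ncol(X),
                 model$scaler$d))
  if (is.null(model$net)) {
    Z <- matrix(0, nrow(X), model$k)
  } else {
    Z <- net_forward(model$net[seq_len(model$n_enc)],
                     apply_scaler(model$scaler, X))$out
  }
  colnames(Z) <- paste0("L", seq_len(model$k))
  Z
}

#' Decode latent features back to the input space
#' @param model an `encoder_model`.
#' @param Z latent matrix with `k` columns.
#' @return matrix in the original (destandardized) feature space.
#' @export
decode <- function(model, Z) {
  stopifnot(inherits(model, "encoder_model"), ncol(Z) == model$k)
  if (is.null(model$net)) {
    scaler <- model$scaler
    return(matrix(scaler$const, nrow(Z), scaler$d, byrow = TRUE))
  }
  dec <- model$net[(model$n_enc + 1L):length(model$net)]
  invert_scaler(model$scaler, net_forward(dec, Z)$out)
}

#' Reconstruction summary of a fitted autoencoder
#'
#' Reports the training-history losses and, when a matrix is supplied, the
#' overall mean squared reconstruction error on it (in standardized units,
#' the training objective) plus per-feature residual summaries in original
#' units.
#'
#' @param model an `encoder_model`.
#' @param X optional matrix to evaluate.
#' @return list with `train_mse`, `val_mse`, `best_epoch`, `history` and,
#'   given `X`, `mse` and `per_feature` (data.frame: bias, rmse per feature).
#' @export
reconstruction_report <- function(model, X = NULL) {
  stopifnot(inherits(model, "encoder_model"))
  h <- model$history
  out <- list(train_mse = h$train_loss[nrow(h)], val_mse = h$val_loss[nrow(h)],
              best_epoch = if (is.null(model$net)) 1L else
                h$epoch[which.min(h$val_loss)],
              history = h)
  if (!is.null(X)) {
    Xhat <- decode(model, encode(model, X))
    resid <- Xhat - X
    if (is.null(model$net)) {
      out$mse <- mean(resid^2)
    } else {
      Xs <- apply_scaler(model$scaler, X)
      out$mse <- mean((net_forward(model$net, Xs)$out - Xs)^2)
    }
    out$per_feature <- data.frame(feature = colnames(X) %||%
                                    paste0("f", seq_len(ncol(X))),
                                  bias = colMeans(resid),
                                  rmse = sqrt(colMeans(resid^2)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a fitted encoder model
#'
#' Persistence round-trips exactly: `load_encoder(save_encoder(m, p))`
#' encodes bit-identically to `m`.
#'
#' @param model an `encoder_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_encoder <- function(model, path) {
  stopifnot(inherits(model, "encoder_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "encoder_model"))
  m
}
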