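# A small synthetic feature matrix with latent structure: three underlying
# factors mixed into 192 observed features plus noise.
latent_matrix <- function(n = 400, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 3), n, 3)
  W <- matrix(rnorm(3 * 192), 3, 192)
  Z %*% W + matrix(rnorm(n * 192, sd = 0.1), n, 192)
}

test_that("standardization round-trips and drops zero-variance features", {
  X <- latent_matrix(150)
  X[, 5] <- 2.5                       # constant feature
  expect_warning(sc <- feature_scaler(X), "zero-variance")
  expect_equal(length(sc$kept), 191L)
  back <- invert_scaler(sc, apply_scaler(sc, X))
  expect_lt(max(abs(back - X)), 1e-9)
})

test_that("latent width honors k and inference is deterministic", {
  X <- latent_matrix(150, seed = 2)
  for (spec in list(c("ae", 3), c("cae", 5), c("ae", 10))) {
    m <- fit_autoencoder(X, spec[1], k = as.integer(spec[2]), epochs = 3,
                         seed = 1)
    Z <- encode(m, X)
    expect_equal(ncol(Z), as.integer(spec[2]))
    expect_identical(Z, encode(m, X))
    expect_equal(ncol(decode(m, Z)), 192L)
  }
  expect_error(fit_autoencoder(X, "ae", k = 192), "smaller than")
  expect_error(fit_autoencoder(X[1:50, ], "ae", k = 3))
  m <- fit_autoencoder(X, "ae", k = 3, epochs = 2, seed = 1)
  expect_error(encode(m, X[, 1:100]), "columns")
})

test_that("constant input reconstructs exactly via dropped-feature handling", {
  X <- matrix(1.25, 120, 192)
  expect_warning(m <- fit_autoencoder(X, "ae", k = 3, epochs = 50, seed = 1),
                 "zero-variance")
  rep <- reconstruction_report(m, X)
  expect_equal(rep$mse, 0)
  expect_equal(decode(m, encode(m, X)), X, ignore_attr = TRUE)
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  X <- latent_matrix(300, seed = 3)
  for (kind in c("ae", "cae")) {
    m1 <- fit_autoencoder(X, kind, k = 3, epochs = 15, seed = 11)
    h <- m1$history
    expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
    m2 <- fit_autoencoder(X, kind, k = 3, epochs = 15, seed = 11)
    expect_identical(m1$history, m2$history)
    expect_identical(encode(m1, X), encode(m2, X))
  }
})

test_that("held-out reconstruction stays within 3x the training MSE", {
  X <- latent_matrix(500, seed = 4)
  m <- fit_autoencoder(X, "ae", k = 5, epochs = 30, seed = 2)
  h <- m$history
  expect_lt(h$val_loss[nrow(h)], 3 * h$train_loss[nrow(h)])
})

test_that("model persistence round-trips bit-identically", {
  X <- latent_matrix(150, seed = 5)
  m <- fit_autoencoder(X, "cae", k = 3, epochs = 3, seed = 9)
  p <- withr::local_tempfile(fileext = ".rds")
  save_encoder(m, p)
  m2 <- load_encoder(p)
  expect_identical(encode(m2, X), encode(m, X))
})

test_that("reconstruction_report matches direct arithmetic on a toy matrix", {
  X <- latent_matrix(120, seed = 6)
  m <- fit_autoencoder(X, "ae", k = 3, epochs = 3, seed = 1)
  rep <- reconstruction_report(m, X)
  Xs <- apply_scaler(m$scaler, X)
  Zs <- vicomp:::net_forward(m$net, Xs)$out
  expect_equal(rep$mse, mean((Zs - Xs)^2))
  Xhat <- decode(m, encode(m, X))
  expect_equal(rep$per_feature$rmse, sqrt(colMeans((Xhat - X)^2)),
               ignore_attr = TRUE)
})
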