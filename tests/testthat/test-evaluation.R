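test_that("point extraction is a direct pixel lookup", {
  set.seed(1)
  v <- array(runif(6 * 5 * 3), c(6, 5, 3))
  v[2, 4, ] <- NA                     # row 2, col 4 masked
  r <- vc_raster(v, bands = c("L1", "L2", "L3"))
  pts <- data.frame(class = c("a", "a", "b", "b", "b"),
                    x = c(0, 3, 2, 2, 9),   # last is out of bounds
                    y = c(0, 1, 4, 4, 0))   # (3,1) hits the masked pixel
  expect_warning(expect_warning(lf <- extract_at_points(r, pts),
                                "outside"), "masked")
  expect_equal(attr(lf, "n_oob"), 1L)
  expect_equal(attr(lf, "n_invalid"), 1L)
  expect_equal(nrow(lf$X), 3L)
  expect_equal(unname(lf$X[1, ]), v[1, 1, ])       # (x=0, y=0)
  ## duplicated point gives duplicated identical rows
  expect_identical(lf$X[2, ], lf$X[3, ])
})

test_that("extraction recovers the generator's label distribution", {
  cfg <- small_config(seed = 3, grid_size = 24, scenes_per_month = 1,
                      cloud_fraction = 0, n_points = 8, noise_sd = 0)
  sim <- simulate_scenes(cfg)
  st <- compute_stack(sim$scenes[[1]])
  lf <- extract_at_points(st, sim$points)
  expect_equal(unname(table(lf$label)), rep(8L, 16L), ignore_attr = TRUE)
})

test_that("rf_top_features ranks a decisive column first", {
  set.seed(5)
  n <- 60
  lab <- rep(1:3, each = n / 3)
  X <- cbind(id = lab, matrix(rnorm(n * 6), n, 6))
  d <- labelled_features(X, lab)
  top <- rf_top_features(d, 2, n_trees = 80, seed = 2)
  expect_equal(attr(top, "selected")[1], 1L)
  expect_equal(ncol(top$X), 2L)
  ## k = d keeps everything, importance-ranked
  all_feats <- rf_top_features(d, ncol(X), n_trees = 20, seed = 2)
  expect_setequal(attr(all_feats, "selected"), seq_len(ncol(X)))
  expect_error(rf_top_features(d, ncol(X) + 1), "exceeds")
  ## determinism
  top2 <- rf_top_features(d, 2, n_trees = 80, seed = 2)
  expect_identical(attr(top, "selected"), attr(top2, "selected"))
})

test_that("percentile CI matches the order-statistic oracle", {
  acc <- seq(0.1, 1.0, by = 0.1)
  expect_equal(unname(percentile_ci(acc, 0.95)), c(0.1, 1.0))
  expect_equal(unname(percentile_ci(acc, 0.5)), ci_oracle(acc, 0.5))
  set.seed(8)
  for (i in 1:20) {
    x <- runif(sample(5:200, 1))
    conf <- runif(1, 0.5, 0.99)
    ci <- percentile_ci(x, conf)
    expect_equal(unname(ci), ci_oracle(x, conf))
    expect_true(ci[1] >= min(x) && ci[2] <= max(x) && ci[1] <= ci[2])
    ## widening the confidence never narrows the interval
    wider <- percentile_ci(x, min(conf + 0.01, 0.999))
    expect_lte(wider[1], ci[1])
    expect_gte(wider[2], ci[2])
  }
})

test_that("bootstrap evaluation: separable data gives a degenerate CI of 1", {
  d <- separable_data(n_per_class = 12, n_classes = 3)
  rep <- bootstrap_evaluate(d, n_boot = 25, seed = 4, n_trees = 30)
  expect_true(all(rep$accuracies == 1))
  expect_equal(c(rep$ci_low, rep$ci_high), c(1, 1))
  expect_true(all(abs(rowSums(rep$importances) - 1) < 1e-12))
  ## determinism
  rep2 <- bootstrap_evaluate(d, n_boot = 25, seed = 4, n_trees = 30)
  expect_identical(rep$accuracies, rep2$accuracies)
  expect_identical(rep$importances, rep2$importances)
})

test_that("bootstrap CI bounds are order statistics of the accuracy sample", {
  set.seed(9)
  d <- separable_data(n_per_class = 10, n_classes = 3, seed = 2)
  d$X[, 1] <- d$X[, 1] + rnorm(nrow(d$X), sd = 6)   # add class overlap
  rep <- bootstrap_evaluate(d, n_boot = 40, seed = 6, n_trees = 30)
  expect_equal(c(rep$ci_low, rep$ci_high),
               ci_oracle(rep$accuracies, 0.95))
  expect_true(all(rep$accuracies >= 0 & rep$accuracies <= 1))
  expect_true(all(!is.na(rep$per_class_recall)))
})

test_that("both resampling modes work and differ", {
  d <- separable_data(n_per_class = 10, n_classes = 3, seed = 3)
  d$X[, 1] <- d$X[, 1] + rnorm(nrow(d$X), sd = 6)
  with_rep <- bootstrap_evaluate(d, n_boot = 10, seed = 1, n_trees = 20,
                                 replacement = TRUE)
  without <- bootstrap_evaluate(d, n_boot = 10, seed = 1, n_trees = 20,
                                replacement = FALSE)
  expect_false(identical(with_rep$accuracies, without$accuracies))
})

test_that("compare_methods emits the methods-by-k table and checks alignment", {
  d <- separable_data(n_per_class = 10, n_classes = 4, n_noise = 6, seed = 4)
  latents <- list(
    CAE = list("2" = labelled_features(d$X[, 1:2], d$label),
               "3" = labelled_features(d$X[, 1:3], d$label)),
    AE = list("2" = labelled_features(d$X[, c(1, 3)], d$label),
              "3" = labelled_features(d$X[, c(1, 3, 4)], d$label)))
  tab <- compare_methods(latents, d, ks = c(2, 3), n_boot = 8, n_trees = 20,
                         seed = 2)
  expect_equal(nrow(tab), 6L)             # 3 methods x 2 ks
  expect_setequal(unique(tab$method), c("CAE", "AE", "RF"))
  expect_true(all(tab$ci_low <= tab$ci_high))
  ## identical feature sets + same seed give identical CIs
  same <- compare_methods(list(A = list("2" = latents$CAE[["2"]]),
                               B = list("2" = latents$CAE[["2"]])),
                          d, ks = 2, n_boot = 8, n_trees = 20, seed = 5)
  expect_equal(same$ci_low[same$method == "A"],
               same$ci_low[same$method == "B"])
  ## misaligned rows are rejected
  bad <- labelled_features(d$X[1:20, 1:2], d$label[1:20])
  expect_error(compare_methods(list(CAE = list("2" = bad)), d, ks = 2),
               "row-aligned")
})
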