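## Quantitative evaluation: extract labelled feature vectors at ground-truth
## points, build the supervised importance baseline, and score feature sets
## with a bootstrap-resampled random-forest protocol and percentile
## confidence intervals.

#' Labelled feature container
#' @param X numeric matrix (points x features).
#' @param label class label per row.
#' @return object of class `labelled_features`.
#' @export
labelled_features <- function(X, label) {
  X <- as.matrix(X)
  label <- factor(label)
  stopifnot(nrow(X) == length(label), !anyNA(label))
  structure(list(X = X, label = label), class = "labelled_features")
}

#' @export
print.labelled_features <- function(x, ...) {
  cat(sprintf("<labelled_features> %d points x %d features, %d classes\n",
              nrow(x$X), ncol(x$X), nlevels(x$label)))
  invisible(x)
}

#' Extract raster values at labelled points
#'
#' Nearest-pixel (direct lookup) sampling at 0-based integer pixel
#' coordinates (`x` = column, `y` = row).  Out-of-bounds points are skipped
#' with a warning; rows containing any masked cell are dropped and reported.
#'
#' @param raster a [vc_raster()].
#' @param points data.frame with columns `class`, `x`, `y`.
#' @return a [labelled_features()] with attributes `n_oob` (points outside
#'   the raster) and `n_invalid` (rows dropped for masked cells).
#' @export
extract_at_points <- function(raster, points) {
  stopifnot(inherits(raster, "vc_raster"),
            all(c("class", "x", "y") %in% names(points)))
  d <- dim(raster)
  x <- round(points$x); y <- round(points$y)
  inb <- x >= 0 & x < d[2] & y >= 0 & y < d[1]
  if (any(!inb))
    warning(sprintf("%d point(s) outside the raster were skipped", sum(!inb)))
  m <- as_pixel_matrix(raster)
  rows <- pixel_index(x[inb], y[inb], d[1], d[2])
  X <- m[rows, , drop = FALSE]
  lab <- points$class[inb]
  ok <- rowSums(is.na(X)) == 0L
  if (any(!ok))
    warning(sprintf("%d point(s) with masked cells were dropped", sum(!ok)))
  out <- labelled_features(X[ok, , drop = FALSE], lab[ok])
  attr(out, "n_oob") <- sum(!inb)
  attr(out, "n_invalid") <- sum(!ok)
  out
}

#' Supervised importance baseline: top-k features by random forest
#'
#' Fits a random forest on all features, ranks them by normalized
#' mean-decrease-impurity importance (ties broken by column order) and
#' returns the top `k` columns — the classical dimensionality-reduction
#' baseline against which the autoencoder latents are compared.
#'
#' @param data a [labelled_features()].
#' @param k number of features to keep (`<= ncol`).
#' @param n_trees,seed forest parameters, see [vc_rf()].
#' @return a [labelled_features()] restricted to the selected columns, with
#'   attributes `selected` (column indices, importance-ranked) and
#'   `importance` (full importance vector).
#' @export
rf_top_features <- function(data, k, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(data, "labelled_features"))
  d <- ncol(data$X)
  if (k > d) stop(sprintf("k = %d exceeds the %d available features", k, d))
  fit <- vc_rf(data$X, data$label, n_trees = n_trees, seed = seed)
  sel <- order(-fit$importance)[seq_len(k)]   # stable: ties keep column order
  out <- labelled_features(data$X[, sel, drop = FALSE], data$label)
  attr(out, "selected") <- sel
  attr(out, "importance") <- fit$importance
  out
}

#' Percentile confidence interval from a sample of statistics
#'
#' Order-statistic (inverse-ECDF) percentiles: the bound at probability `p`
#' is `sorted(x)[ceiling(n * p)]`, so both bounds are elements of `x`.
#'
#' @param x numeric vector (e.g. bootstrap accuracies).
#' @param confidence central coverage, e.g. `0.95`.
#' @return named numeric `c(low, high)`.
#' @export
percentile_ci <- function(x, confidence = 0.95) {
  stopifnot(length(x) >= 1, confidence > 0, confidence < 1)
  s <- sort(x)
  n <- length(s)
  alpha <- 1 - confidence
  lo <- s[max(1L, ceiling(n * alpha / 2))]
  hi <- s[ceiling(n * (1 - alpha / 2))]
  c(low = lo, high = hi)
}

#' Bootstrap-resampled random-forest evaluation
#'
#' Repeats `n_boot` times: resample the `n` labelled rows with replacement to
#' size `n` (or permute them, with `replacement = FALSE`), split the sample
#' into `train_fraction` / `1 - train_fraction` parts (rows not drawn into
#' the sample are not reused), fit a random forest on the training part and
#' record overall accuracy on the test part together with the fitted
#' importance vector.  Iterations whose test part holds fewer than two
#' classes are redrawn (a warning is raised if more than 10% of iterations
#' needed redraws).  The confidence interval is the percentile interval of
#' the accuracy sample.
#'
#' @param data a [labelled_features()] with at least 2 classes and 8 rows.
#' @param n_boot bootstrap iterations (1000 in the reference protocol).
#' @param train_fraction training share of each resample (0.75).
#' @param confidence CI coverage (0.95).
#' @param seed RNG seed.
#' @param replacement resample with replacement (`TRUE`, the bootstrap) or
#'   plain repeated 75/25 splits (`FALSE`).
#' @param n_trees trees per forest.
#' @return object of class `bootstrap_report`: `accuracies`, `ci_low`,
#'   `ci_high`, `mean_accuracy`, `importances` (`n_boot x d`, rows sum to 1),
#'   `per_class_recall` (mean over iterations), `redraws`, `config`.
#' @export
bootstrap_evaluate <- function(data, n_boot = 1000L, train_fraction = 0.75,
                               confidence = 0.95, seed = 1L,
                               replacement = TRUE, n_trees = 500L) {
  stopifnot(inherits(data, "labelled_features"))
  n <- nrow(data$X)
  if (n < 8) stop("need at least 8 labelled rows")
  if (nlevels(droplevels(data$label)) < 2) stop("need at least 2 classes")
  set.seed(seed)
  d <- ncol(data$X)
  acc <- numeric(n_boot)
  imps <- matrix(NA_real_, n_boot, d,
                 dimnames = list(NULL, colnames(data$X)))
  recall <- matrix(NA_real_, n_boot, nlevels(data$label),
                   dimnames = list(NULL, levels(data$label)))
  n_train <- round(train_fraction * n)
  redraws <- 0L
  for (it in seq_len(n_boot)) {
    repeat {
      samp <- if (replacement) sample.int(n, n, replace = TRUE) else
        sample.int(n)
      tr <- samp[seq_len(n_train)]
      te <- samp[(n_train + 1L):n]
      if (nlevels(droplevels(data$label[te])) >= 2 &&
          nlevels(droplevels(data$label[tr])) >= 2) break
      redraws <- redraws + 1L
    }
    fit <- vc_rf(data$X[tr, , drop = FALSE], data$label[tr],
                 n_trees = n_trees,
                 seed = sample.int(.Machine$integer.max, 1L))
    pred <- predict(fit, data$X[te, , drop = FALSE])
    truth <- factor(data$label[te], levels = fit$classes)
    acc[it] <- mean(as.character(pred) == as.character(truth))
    imps[it, ] <- as.numeric(fit$importance)   # same columns, same order
    for (cl in levels(data$label)) {
      in_cl <- as.character(truth) == cl
      if (any(in_cl))
        recall[it, cl] <- mean(as.character(pred)[in_cl] == cl)
    }
  }
  if (redraws > 0.1 * n_boot)
    warning(sprintf("%d redraw(s) over %d iterations (> 10%%): classes may be too sparse",
                    redraws, n_boot))
  ci <- percentile_ci(acc, confidence)
  structure(list(accuracies = acc, ci_low = unname(ci["low"]),
                 ci_high = unname(ci["high"]), mean_accuracy = mean(acc),
                 importances = imps,
                 per_class_recall = colMeans(recall, na.rm = TRUE),
                 redraws = redraws,
                 config = list(n_boot = n_boot,
                               train_fraction = train_fraction,
                               confidence = confidence, seed = seed,
                               replacement = replacement,
                               n_trees = n_trees)),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("<bootstrap_report> %d iterations, mean accuracy %.3f, %.0f%% CI [%.3f, %.3f]\n",
              x$config$n_boot, x$mean_accuracy, 100 * x$config$confidence,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Compare compressed feature sets across methods and latent dimensions
#'
#' For each latent dimension `k`, evaluates the supplied autoencoder latents
#' and the `rf_top_features` baseline (computed here from the raw features)
#' with [bootstrap_evaluate()], and tabulates the confidence intervals — the
#' methods-by-dimensions accuracy table of the evaluation protocol.
#'
#' @param latents_by_method named list (method name, e.g. `"CAE"`, `"AE"`) of
#'   named lists (`as.character(k)`) of [labelled_features()], all
#'   row-aligned with `raw`.
#' @param raw the full-width [labelled_features()] (e.g. 192 features).
#' @param ks latent dimensions to evaluate.
#' @param n_boot,train_fraction,confidence,seed,n_trees passed to
#'   [bootstrap_evaluate()].
#' @return data.frame with columns `method`, `k`, `mean_accuracy`, `ci_low`,
#'   `ci_high`; the per-method reports are attached as attribute `reports`.
#' @export
compare_methods <- function(latents_by_method, raw, ks = c(3, 5, 10),
                            n_boot = 1000L, train_fraction = 0.75,
                            confidence = 0.95, seed = 1L, n_trees = 500L) {
  stopifnot(inherits(raw, "labelled_features"))
  for (m in names(latents_by_method))
    for (kk in names(latents_by_method[[m]])) {
      lf <- latents_by_method[[m]][[kk]]
      stopifnot(inherits(lf, "labelled_features"))
      if (nrow(lf$X) != nrow(raw$X) ||
          !identical(as.character(lf$label), as.character(raw$label)))
        stop(sprintf("feature set %s/k=%s is not row-aligned with the raw features",
                     m, kk))
    }
  rows <- list()
  reports <- list()
  for (k in ks) {
    sets <- lapply(latents_by_method, `[[`, as.character(k))
    sets[[sprintf("RF-top-%d", k)]] <-
      rf_top_features(raw, k, n_trees = n_trees, seed = seed)
    for (m in names(sets)) {
      if (is.null(sets[[m]]))
        stop(sprintf("method %s has no latents for k = %d", m, k))
      rep <- bootstrap_evaluate(sets[[m]], n_boot = n_boot,
                                train_fraction = train_fraction,
                                confidence = confidence, seed = seed,
                                n_trees = n_trees)
      rows[[length(rows) + 1L]] <-
        data.frame(method = sub("-top-.*$", "", m), k = k,
                   mean_accuracy = rep$mean_accuracy,
                   ci_low = rep$ci_low, ci_high = rep$ci_high,
                   stringsAsFactors = FALSE)
      reports[[paste(m, k, sep = "_")]] <- rep
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
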