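#' Random-forest classifier
#'
#' Bagged CART classification trees on the Gini criterion with per-node
#' feature subsampling, as used both for the supervised evaluation of
#' compressed features and for the impurity-importance baseline.  Variable
#' importance is total weighted impurity decrease, normalized to sum to 1.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y class labels (coerced to factor).
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split (default `floor(sqrt(ncol(X)))`).
#' @param min_node minimum samples per leaf.
#' @param max_depth maximum tree depth, `0` = unlimited.
#' @param seed integer seed for the forest's own RNG (independent of R's
#'   RNG stream).
#' @return object of class `vc_rf` with elements `forest`, `classes`,
#'   `importance` (named, sums to 1).
#' @export
vc_rf <- function(X, y, n_trees = 500L, mtry = NULL, min_node = 1L,
                  max_depth = 0L, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- factor(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2, nlevels(y) >= 1)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  mtry <- min(as.integer(mtry), ncol(X))
  fit <- .rf_fit_cpp(X, as.integer(y) - 1L, nlevels(y), as.integer(n_trees),
                     mtry, as.integer(min_node), as.integer(max_depth),
                     as.integer(seed))
  imp <- as.numeric(fit$importance)
  names(imp) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  structure(list(forest = fit, classes = levels(y), importance = imp,
                 n_trees = n_trees, mtry = mtry, seed = seed),
            class = "vc_rf")
}

#' @export
print.vc_rf <- function(x, ...) {
  cat(sprintf("<vc_rf> %d trees, mtry %d, %d classes\n", x$n_trees, x$mtry,
              length(x$classes)))
  invisible(x)
}

#' @param object a `vc_rf` model.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @rdname vc_rf
#' @export
predict.vc_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  idx <- .rf_predict_cpp(object$forest, newdata)
  factor(object$classes[idx + 1L], levels = object$classes)
}
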