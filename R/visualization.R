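## Visual outputs: 3-D scatter of latent features coloured by class, and
## 8-bit RGB false-colour rendering of a 3-band latent raster.

#' Deterministic class colour palette
#' @param classes character vector of class names.
#' @return named vector of hex colours, stable for a given class vector.
#' @export
class_palette <- function(classes) {
  classes <- as.character(classes)
  cols <- grDevices::hcl(h = seq(15, 375, length.out = length(classes) + 1L)[
    seq_along(classes)], c = 100, l = 60)
  names(cols) <- classes
  cols
}

#' 3-D scatter plot of latent features by class
#'
#' Plots the first three latent dimensions of each labelled point, one
#' colour and legend entry per class (deterministic class-colour mapping),
#' and writes the figure to a PNG file.
#'
#' @param latents a [labelled_features()] with at least 3 feature columns.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
scatter3d <- function(latents, path, width = 900, height = 700,
                      main = "Latent features by class") {
  stopifnot(inherits(latents, "labelled_features"))
  if (ncol(latents$X) < 3)
    stop("3-D scatter needs at least 3 latent dimensions")
  cls <- levels(latents$label)
  pal <- class_palette(cls)
  df <- data.frame(L1 = latents$X[, 1], L2 = latents$X[, 2],
                   L3 = latents$X[, 3], class = latents$label)
  fig <- lattice::cloud(
    L3 ~ L1 * L2, data = df, groups = df$class,
    par.settings = list(superpose.symbol = list(col = pal, pch = 16,
                                                cex = 0.5)),
    auto.key = list(space = "right", cex = 0.7), main = main)
  grDevices::png(path, width = width, height = height, type = "cairo")
  print(fig)
  grDevices::dev.off()
  invisible(path)
}

#' Percentile stretch parameters for a latent raster
#'
#' @param raster a [vc_raster()].
#' @param probs lower/upper percentile cuts (default 2nd and 98th).
#' @return matrix `nband x 2` of `(low, high)` cut values.
#' @export
stretch_params <- function(raster, probs = c(0.02, 0.98)) {
  stopifnot(inherits(raster, "vc_raster"), length(probs) == 2,
            probs[1] < probs[2])
  m <- as_pixel_matrix(raster)
  t(apply(m, 2, function(v) {
    q <- quantile(v, probs, na.rm = TRUE, names = FALSE)
    c(low = q[1], high = q[2])
  }))
}

#' False-colour 8-bit RGB rendering of a 3-band raster
#'
#' Each band is linearly rescaled from its `(low, high)` stretch window to
#' `[0, 255]` and clipped; band 1 maps to red, 2 to green, 3 to blue.
#' Masked pixels render as 0; a degenerate window (`low == high`) renders
#' the band as constant mid-gray 127.
#'
#' @param raster a 3-band [vc_raster()] (e.g. `k = 3` latents).
#' @param stretch optional `3 x 2` matrix of `(low, high)` cuts; defaults to
#'   the 2-98 percentile window of each band ([stretch_params()]).
#' @return integer array `nrow x ncol x 3` with values in `0..255`.
#' @export
rgb_composite <- function(raster, stretch = NULL) {
  stopifnot(inherits(raster, "vc_raster"))
  if (dim(raster)[3] != 3L)
    stop("rgb_composite needs exactly 3 bands; select 3 latent channels first")
  if (is.null(stretch)) stretch <- stretch_params(raster)
  stopifnot(nrow(stretch) == 3L, ncol(stretch) == 2L)
  d <- dim(raster)
  out <- array(0L, c(d[1], d[2], 3L))
  for (b in 1:3) {
    v <- raster$values[, , b]
    lo <- stretch[b, 1]; hi <- stretch[b, 2]
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
      scaled <- matrix(127L, d[1], d[2])
      scaled[is.na(v)] <- 0L
    } else {
      scaled <- round(pmin(pmax((v - lo) / (hi - lo), 0), 1) * 255)
      scaled[is.na(scaled)] <- 0
      storage.mode(scaled) <- "integer"
    }
    out[, , b] <- scaled
  }
  out
}

#' Write an RGB array as a PNG image
#'
#' @param rgb integer array `nrow x ncol x 3` in `0..255` (from
#'   [rgb_composite()]).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  d <- dim(rgb)
  grDevices::png(path, width = d[2], height = d[1], type = "cairo")
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  hex <- grDevices::rgb(rgb[, , 1], rgb[, , 2], rgb[, , 3],
                        maxColorValue = 255)
  graphics::rasterImage(grDevices::as.raster(matrix(hex, d[1], d[2])),
                        0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
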