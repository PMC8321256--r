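## Monthly median compositing: collapse all dated 16-index stacks into one
## 192-band annual raster (12 months x 16 indices, month-major), the feature
## vector fed to the autoencoders.

#' Band names of the 192-layer composite, month-major
#' @return character vector `m01_ARVI ... m12_VARI` of length 192.
#' @export
composite_band_names <- function() {
  as.vector(t(outer(sprintf("m%02d", 1:12), index_names(), paste, sep = "_")))
}

## median over unmasked values as explicit order statistics; the even case is
## the mean of the two central order statistics
cell_median <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) return(NA_real_)
  s <- sort(v)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

#' Monthly median composite of dated index stacks
#'
#' For every pixel, calendar month and index, takes the median over all
#' unmasked observations of that index among the scenes acquired in that
#' month (all years pooled).  Even observation counts use the mean of the two
#' central order statistics.  Cells with no unmasked observation are `NA`.
#'
#' @param stacks list of 16-band [vc_raster()]s with dates (as produced by
#'   [compute_stack()]); all must share the grid.
#' @return a 192-band `vc_raster` in month-major order
#'   ([composite_band_names()]), with a `provenance` attribute giving the
#'   number of scenes contributing to each month.
#' @export
monthly_median <- function(stacks) {
  stopifnot(length(stacks) >= 1)
  d0 <- dim(stacks[[1]])
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    stopifnot(inherits(s, "vc_raster"))
    if (!identical(dim(s)[1:2], d0[1:2]))
      stop(sprintf("stack %d grid (%d x %d) does not match stack 1 (%d x %d)",
                   i, dim(s)[1], dim(s)[2], d0[1], d0[2]))
    if (is.null(s$date)) stop(sprintf("stack %d has no date", i))
    if (dim(s)[3] != 16L) stop(sprintf("stack %d does not have 16 layers", i))
  }
  months <- vapply(stacks, function(s) as.integer(format(s$date, "%m")), 0L)
  npix <- d0[1] * d0[2]
  out <- matrix(NA_real_, npix, 192L, dimnames = list(NULL, composite_band_names()))
  prov <- integer(12L)
  for (m in 1:12) {
    idx <- which(months == m)
    prov[m] <- length(idx)
    if (!length(idx)) next
    ## n_obs x npix x 16 stack for this month
    cols <- (m - 1L) * 16L + seq_len(16L)
    if (length(idx) == 1L) {
      out[, cols] <- as_pixel_matrix(stacks[[idx]])
    } else {
      arr <- vapply(idx, function(i) as_pixel_matrix(stacks[[i]]),
                    matrix(0, npix, 16L))            # npix x 16 x n_obs
      out[, cols] <- apply(arr, c(1, 2), cell_median)
    }
  }
  out[is.nan(out)] <- NA_real_
  r <- from_pixel_matrix(out, d0[1], d0[2], bands = composite_band_names())
  attr(r, "provenance") <- prov
  r
}

#' Fill gaps in a monthly composite by temporal interpolation
#'
#' Invalid (masked) cells are filled per pixel and per index by linear
#' interpolation across months, with nearest-value extrapolation before the
#' first and after the last valid month.  Pixels having an index with no
#' valid month at all cannot be filled; they are left `NA` across that index
#' and flagged for exclusion from downstream training.
#'
#' @param comp a 192-band composite from [monthly_median()].
#' @return a 192-band `vc_raster` with attributes `fill_count` (number of
#'   cells interpolated) and `dropped` (logical vector over row-major pixels:
#'   `TRUE` where an index had zero valid months).
#' @export
fill_gaps <- function(comp) {
  stopifnot(inherits(comp, "vc_raster"), dim(comp)[3] == 192L)
  m <- as_pixel_matrix(comp)
  npix <- nrow(m)
  filled <- 0L
  dropped <- logical(npix)
  na_rows <- which(rowSums(is.na(m)) > 0L)
  for (p in na_rows) {
    v <- matrix(m[p, ], nrow = 16L)       # 16 indices x 12 months
    for (j in seq_len(16L)) {
      ok <- which(!is.na(v[j, ]))
      if (length(ok) == 12L) next
      if (length(ok) == 0L) { dropped[p] <- TRUE; next }
      filled <- filled + (12L - length(ok))
      v[j, ] <- if (length(ok) == 1L) v[j, ok] else
        approx(ok, v[j, ok], xout = 1:12, rule = 2)$y
    }
    m[p, ] <- as.vector(v)
  }
  r <- from_pixel_matrix(m, dim(comp)[1], dim(comp)[2],
                         bands = composite_band_names())
  attr(r, "fill_count") <- filled
  attr(r, "dropped") <- dropped
  attr(r, "provenance") <- attr(comp, "provenance")
  r
}
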