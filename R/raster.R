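#' @useDynLib vicomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx median quantile rnorm runif sd
#' @importFrom utils read.csv write.csv
NULL

#' Multiband raster container
#'
#' A minimal in-memory raster: a numeric `nrow x ncol x nband` array with
#' named bands, an optional acquisition date, and `NA` as the nodata/mask
#' value.  Pixel coordinates are 0-based `(x, y)` with `x` the column and `y`
#' the row, matching the ground-truth CSV convention.
#'
#' @param values numeric array of dimension `c(nrow, ncol, nband)`, or a
#'   matrix for a single band.
#' @param bands character vector of band names, length `nband`.
#' @param date optional `Date` (acquisition date of the scene).
#' @return an object of class `vc_raster`.
#' @export
vc_raster <- function(values, bands, date = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (missing(bands)) bands <- dimnames(values)[[3]]
  if (is.null(bands)) bands <- paste0("band", seq_len(dim(values)[3]))
  if (length(bands) != dim(values)[3])
    stop("length(bands) must equal the number of layers")
  dimnames(values) <- list(NULL, NULL, bands)
  storage.mode(values) <- "double"
  structure(list(values = values, bands = bands, date = date),
            class = "vc_raster")
}

#' @export
dim.vc_raster <- function(x) dim(x$values)

#' @export
print.vc_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vc_raster> %d x %d pixels, %d band(s)%s\n", d[1], d[2], d[3],
              if (!is.null(x$date)) paste0(", date ", format(x$date)) else ""))
  cat("bands:", paste(utils::head(x$bands, 8), collapse = ", "),
      if (d[3] > 8) "..." else "", "\n")
  invisible(x)
}

n_bands <- function(r) dim(r$values)[3]

#' Extract one band as a matrix
#' @param r a `vc_raster`.
#' @param band band name or index.
#' @return numeric matrix `nrow x ncol`.
#' @export
band_matrix <- function(r, band) {
  stopifnot(inherits(r, "vc_raster"))
  r$values[, , band, drop = TRUE]
}

#' Flatten a raster to a pixel-by-band matrix
#'
#' Pixels are ordered row-major (row 1 left-to-right, then row 2, ...), the
#' fixed pixel ordering used throughout the package so that feature matrices
#' and rasters stay row-aligned.
#'
#' @param r a `vc_raster`.
#' @return numeric matrix `n_pixels x nband` with band names as colnames.
#' @export
as_pixel_matrix <- function(r) {
  d <- dim(r$values)
  ## aperm so pixel index runs row-major
  m <- matrix(aperm(r$values, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- r$bands
  m
}

#' Rebuild a raster from a pixel-by-band matrix
#' @param m matrix as produced by [as_pixel_matrix()].
#' @param nrow,ncol raster dimensions.
#' @param bands band names (defaults to `colnames(m)`).
#' @param date optional date.
#' @return a `vc_raster`.
#' @export
from_pixel_matrix <- function(m, nrow, ncol, bands = colnames(m), date = NULL) {
  stopifnot(base::nrow(m) == nrow * ncol)
  a <- aperm(array(m, c(ncol, nrow, base::ncol(m))), c(2, 1, 3))
  vc_raster(a, bands = bands, date = date)
}

## pixel index (row-major) for 0-based x (col), y (row)
pixel_index <- function(x, y, nrow, ncol) y * ncol + x + 1L

#' Write a raster to a plain-text file
#'
#' Serialization is a small header of `#key value` lines (`nrow`, `ncol`,
#' `bands`, optional `date`) followed by a TSV matrix with one row per pixel
#' (row-major order) and one column per band; masked cells are `NA`.  A
#' text-based stand-in for multiband GeoTIFF, which keeps the interchange
#' format dependency-free.
#'
#' @param r a `vc_raster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "vc_raster"))
  d <- dim(r$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#nrow %d", d[1]), sprintf("#ncol %d", d[2]),
               paste("#bands", paste(r$bands, collapse = "\t"))), con)
  if (!is.null(r$date)) writeLines(paste("#date", format(r$date)), con)
  utils::write.table(format(as_pixel_matrix(r), digits = 17, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#' @param path file path.
#' @return a `vc_raster`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- strsplit(sub("^#", "", lines[hdr]), "[ \t]", perl = TRUE)
  keys <- vapply(meta, `[[`, "", 1L)
  val <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) NULL else meta[[i]][-1L]
  }
  nr <- as.integer(val("nrow")); nc <- as.integer(val("ncol"))
  bands <- val("bands")
  date <- if (!is.null(val("date"))) as.Date(val("date")) else NULL
  m <- as.matrix(utils::read.table(text = lines[-hdr], sep = "\t",
                                   colClasses = "numeric"))
  colnames(m) <- bands
  from_pixel_matrix(m, nr, nc, bands = bands, date = date)
}
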