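## Sixteen spectral vegetation indices computed from six surface-reflectance
## band roles: Blue (B), Green (G), Red (R), RedEdge1 (RE1), RedEdge3 (RE3)
## and NIR (N).  The registry order is fixed (alphabetical ARVI..VARI) and is
## the layer order of every index stack produced by the package.

## Each entry: numerator and denominator as functions of the band list, so
## near-zero denominators can be masked uniformly.  Indices that are not a
## single fraction (MSAVI, GCI) supply `value` directly with `den` for the
## mask rule where relevant.
index_registry <- function() {
  list(
    ## Atmospherically resistant VI, Kaufman-Tanre form with gamma = 1:
    ## rb = 2R - B.  (The source table's typeset fraction is ambiguous.)
    ARVI    = list(num = function(b) b$N - (2 * b$R - b$B),
                   den = function(b) b$N + (2 * b$R - b$B)),
    EVI     = list(num = function(b) 2.5 * (b$N - b$R),
                   den = function(b) (b$N + 6 * b$R - 7.5 * b$B) + 1),
    GARI    = list(num = function(b) b$N - (b$G - 1.7 * (b$B - b$R)),
                   den = function(b) b$N + (b$G - 1.7 * (b$B - b$R))),
    ## As printed in the source table: N/R - 1 (not N/G - 1).
    GCI     = list(num = function(b) b$N - b$R,
                   den = function(b) b$R),
    GLI     = list(num = function(b) (b$G - b$R) + (b$G - b$B),
                   den = function(b) 2 * b$G + b$R + b$B),
    GNDVI   = list(num = function(b) b$N - b$G,
                   den = function(b) b$N + b$G),
    GRVI    = list(num = function(b) b$G - b$R,
                   den = function(b) b$G + b$R),
    MRENDVI = list(num = function(b) b$RE3 - b$RE1,
                   den = function(b) b$RE3 + b$RE1 - 2 * b$B),
    MRESR   = list(num = function(b) b$RE3 - b$B,
                   den = function(b) b$RE1 - b$B),
    MSAVI   = list(value = function(b)
                     (2 * b$N + 1 - sqrt((2 * b$N + 1)^2 - 8 * (b$N - b$R))) / 2),
    NDVI    = list(num = function(b) b$N - b$R,
                   den = function(b) b$N + b$R),
    OSAVI   = list(num = function(b) b$N - b$R,
                   den = function(b) b$N + b$R + 0.16),
    RENDVI  = list(num = function(b) b$RE3 - b$RE1,
                   den = function(b) b$RE3 + b$RE1),
    SAVI    = list(num = function(b) 1.5 * (b$N - b$R),
                   den = function(b) b$N + b$R + 0.5),
    SIPI    = list(num = function(b) b$N - b$B,
                   den = function(b) b$N - b$R),
    VARI    = list(num = function(b) b$G - b$R,
                   den = function(b) b$G + b$R - b$B)
  )
}

#' Names of the sixteen vegetation indices, in registry order
#' @return character vector of length 16.
#' @export
index_names <- function() names(index_registry())

DEN_EPS <- 1e-12   # |denominator| below this masks the single index value

#' Compute one vegetation index
#'
#' Evaluates the named index from the six band-role reflectances.  All
#' arguments are vectorized.  A near-zero denominator (absolute value below
#' `1e-12`) yields `NA` for that value rather than an error, so one
#' degenerate index never invalidates the other fifteen.
#'
#' @param name one of [index_names()].
#' @param b Blue, `g` Green, `r` Red, `re1` RedEdge1, `re3` RedEdge3,
#'   `n` NIR surface reflectance (dimensionless).
#' @param g,r,re1,re3,n see `b`.
#' @return numeric vector of index values (`NA` where masked).
#' @export
compute_index <- function(name, b, g, r, re1, re3, n) {
  reg <- index_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown index '%s'; see index_names()", name))
  bands <- list(B = b, G = g, R = r, RE1 = re1, RE3 = re3, N = n)
  e <- reg[[name]]
  if (!is.null(e$value)) return(e$value(bands))
  den <- e$den(bands)
  out <- e$num(bands) / den
  out[!is.na(den) & abs(den) < DEN_EPS] <- NA_real_
  out
}

#' Compute the 16-index stack for one scene
#'
#' Produces a 16-band raster in the fixed registry order.  The input mask is
#' propagated: a pixel masked in the scene is masked in all sixteen index
#' layers.  Pixels whose reflectance falls outside `[-0.1, 2]` in any band
#' are treated as corrupt and masked likewise.  Per-index masked-cell counts
#' (beyond the input mask) are attached as the `masked_counts` attribute.
#'
#' @param scene a six-band [vc_raster()] whose bands include the roles
#'   `B, G, R, RE1, RE3, N` (extra bands ignored).
#' @return a 16-band `vc_raster` carrying the scene's date.
#' @export
compute_stack <- function(scene) {
  stopifnot(inherits(scene, "vc_raster"))
  missing_roles <- setdiff(BAND_ROLES, scene$bands)
  if (length(missing_roles))
    stop(sprintf("scene is missing band role(s): %s",
                 paste(missing_roles, collapse = ", ")))
  m <- as_pixel_matrix(scene)[, BAND_ROLES, drop = FALSE]
  bad <- rowSums(is.na(m)) > 0 |
    rowSums(m < -0.1 | m > 2, na.rm = TRUE) > 0
  m[bad, ] <- NA_real_
  bl <- list(B = m[, "B"], G = m[, "G"], R = m[, "R"],
             RE1 = m[, "RE1"], RE3 = m[, "RE3"], N = m[, "N"])
  nm <- index_names()
  out <- matrix(NA_real_, nrow(m), 16L, dimnames = list(NULL, nm))
  for (j in nm)
    out[, j] <- compute_index(j, bl$B, bl$G, bl$R, bl$RE1, bl$RE3, bl$N)
  r <- from_pixel_matrix(out, dim(scene)[1], dim(scene)[2], bands = nm,
                         date = scene$date)
  attr(r, "masked_counts") <- colSums(is.na(out)) - sum(bad)
  r
}
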