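# Independent oracles, written before (and kept independent of) the code
# paths they check.

# Each index formula as one literal arithmetic expression of the six band
# reflectances, in registry order.
index_oracle <- list(
  ARVI    = function(B, G, R, RE1, RE3, N) (N - (2*R - B)) / (N + (2*R - B)),
  EVI     = function(B, G, R, RE1, RE3, N) 2.5 * (N - R) / ((N + 6*R - 7.5*B) + 1),
  GARI    = function(B, G, R, RE1, RE3, N) (N - (G - 1.7*(B - R))) / (N + (G - 1.7*(B - R))),
  GCI     = function(B, G, R, RE1, RE3, N) N / R - 1,
  GLI     = function(B, G, R, RE1, RE3, N) ((G - R) + (G - B)) / (2*G + R + B),
  GNDVI   = function(B, G, R, RE1, RE3, N) (N - G) / (N + G),
  GRVI    = function(B, G, R, RE1, RE3, N) (G - R) / (G + R),
  MRENDVI = function(B, G, R, RE1, RE3, N) (RE3 - RE1) / (RE3 + RE1 - 2*B),
  MRESR   = function(B, G, R, RE1, RE3, N) (RE3 - B) / (RE1 - B),
  MSAVI   = function(B, G, R, RE1, RE3, N) (2*N + 1 - sqrt((2*N + 1)^2 - 8*(N - R))) / 2,
  NDVI    = function(B, G, R, RE1, RE3, N) (N - R) / (N + R),
  OSAVI   = function(B, G, R, RE1, RE3, N) (N - R) / (N + R + 0.16),
  RENDVI  = function(B, G, R, RE1, RE3, N) (RE3 - RE1) / (RE3 + RE1),
  SAVI    = function(B, G, R, RE1, RE3, N) 1.5 * (N - R) / (N + R + 0.5),
  SIPI    = function(B, G, R, RE1, RE3, N) (N - B) / (N - R),
  VARI    = function(B, G, R, RE1, RE3, N) (G - R) / (G + R - B)
)

# Denominator of each fractional index, for filtering degenerate random
# pixels when comparing against the oracle.
index_oracle_den <- list(
  ARVI    = function(B, G, R, RE1, RE3, N) N + (2*R - B),
  EVI     = function(B, G, R, RE1, RE3, N) (N + 6*R - 7.5*B) + 1,
  GARI    = function(B, G, R, RE1, RE3, N) N + (G - 1.7*(B - R)),
  GCI     = function(B, G, R, RE1, RE3, N) R,
  GLI     = function(B, G, R, RE1, RE3, N) 2*G + R + B,
  GNDVI   = function(B, G, R, RE1, RE3, N) N + G,
  GRVI    = function(B, G, R, RE1, RE3, N) G + R,
  MRENDVI = function(B, G, R, RE1, RE3, N) RE3 + RE1 - 2*B,
  MRESR   = function(B, G, R, RE1, RE3, N) RE1 - B,
  NDVI    = function(B, G, R, RE1, RE3, N) N + R,
  OSAVI   = function(B, G, R, RE1, RE3, N) N + R + 0.16,
  RENDVI  = function(B, G, R, RE1, RE3, N) RE3 + RE1,
  SAVI    = function(B, G, R, RE1, RE3, N) N + R + 0.5,
  SIPI    = function(B, G, R, RE1, RE3, N) N - R,
  VARI    = function(B, G, R, RE1, RE3, N) G + R - B
)

# Random valid reflectance pixels whose fractional denominators all stay
# away from zero (degenerate denominators are exercised separately by the
# masking tests).
random_band_pixels <- function(n, seed = 1, den_floor = 1e-3) {
  set.seed(seed)
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    m <- matrix(runif(6 * n * 2), ncol = 6,
                dimnames = list(NULL, c("B", "G", "R", "RE1", "RE3", "N")))
    keep <- rep(TRUE, nrow(m))
    for (f in index_oracle_den)
      keep <- keep & abs(f(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6])) >
        den_floor
    out <- rbind(out, m[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Sort-based per-cell median oracle for monthly compositing: loops over
# pixels, months and indices, sorts the unmasked observations and applies
# the order-statistic definition directly.
composite_oracle <- function(stacks) {
  months <- vapply(stacks, function(s) as.integer(format(s$date, "%m")), 0L)
  d <- dim(stacks[[1]])
  npix <- d[1] * d[2]
  mats <- lapply(stacks, vicomp::as_pixel_matrix)
  out <- matrix(NA_real_, npix, 192)
  for (m in 1:12) {
    sel <- which(months == m)
    if (!length(sel)) next
    for (p in seq_len(npix)) {
      for (j in 1:16) {
        v <- vapply(sel, function(i) mats[[i]][p, j], 0)
        v <- sort(v[!is.na(v)])
        nv <- length(v)
        if (nv == 0) next
        out[p, (m - 1) * 16 + j] <-
          if (nv %% 2 == 1) v[(nv + 1) / 2] else (v[nv / 2] + v[nv / 2 + 1]) / 2
      }
    }
  }
  out
}

# Order-statistic percentile oracle (inverse ECDF).
ci_oracle <- function(x, confidence) {
  s <- sort(x)
  n <- length(s)
  a <- 1 - confidence
  c(s[max(1, ceiling(n * a / 2))], s[ceiling(n * (1 - a / 2))])
}
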