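## Synthetic Sentinel-2-like world: class-specific seasonal reflectance
## trajectories on a tiled grid, with Gaussian noise and cloud masking, so the
## whole pipeline (indices -> composites -> encoders -> evaluation) can be
## exercised without any satellite download.

BAND_ROLES <- c("B", "G", "R", "RE1", "RE3", "N")

#' Create a class profile
#'
#' A class profile holds the expected surface reflectance of one vegetation
#' (or non-vegetation) type for each calendar month and each of the six band
#' roles (Blue, Green, Red, RedEdge1, RedEdge3, NIR), plus the per-band noise
#' level and the number of ground-truth points to draw for the class.
#'
#' @param class_name class label.
#' @param monthly_means `12 x 6` matrix of mean reflectance in `[0, 1]`
#'   (rows = months, columns = band roles B, G, R, RE1, RE3, N).
#' @param noise_sd per-band reflectance standard deviation (scalar recycled to
#'   6, or length-6 vector); must be `>= 0`.
#' @param n_points number of ground-truth points (`>= 1`).
#' @return an object of class `class_profile`.
#' @export
class_profile <- function(class_name, monthly_means, noise_sd = 0.02,
                          n_points = 300L) {
  monthly_means <- as.matrix(monthly_means)
  stopifnot(identical(dim(monthly_means), c(12L, 6L)),
            all(is.finite(monthly_means)),
            all(monthly_means >= 0 & monthly_means <= 1))
  noise_sd <- rep_len(as.numeric(noise_sd), 6L)
  stopifnot(all(noise_sd >= 0), n_points >= 1)
  colnames(monthly_means) <- BAND_ROLES
  structure(list(class_name = as.character(class_name),
                 monthly_means = monthly_means,
                 noise_sd = noise_sd,
                 n_points = as.integer(n_points)),
            class = "class_profile")
}

## Seasonal greenness curve: baseline plus a Gaussian bell over months.
## peak in month units, width in months; values clipped to [0, 1].
greenness_curve <- function(base, amp, peak, width) {
  m <- 1:12
  pmin(pmax(base + amp * exp(-0.5 * ((m - peak) / width)^2), 0), 1)
}

## Mix a background spectrum and a green-vegetation spectrum by greenness.
## spectra are length-6 (B, G, R, RE1, RE3, N).
mix_spectra <- function(g, background, vegetation) {
  mm <- outer(1 - g, background) + outer(g, vegetation)
  colnames(mm) <- BAND_ROLES
  mm
}

SPEC_GREEN <- c(B = 0.030, G = 0.060, R = 0.035, RE1 = 0.110, RE3 = 0.300,
                N = 0.360)
SPEC_SOIL  <- c(B = 0.090, G = 0.110, R = 0.130, RE1 = 0.160, RE3 = 0.200,
                N = 0.220)
SPEC_WET   <- c(B = 0.060, G = 0.080, R = 0.085, RE1 = 0.100, RE3 = 0.120,
                N = 0.130)
SPEC_WATER <- c(B = 0.050, G = 0.045, R = 0.030, RE1 = 0.022, RE3 = 0.018,
                N = 0.015)

#' Default 16-class profile set
#'
#' Returns profiles for the sixteen vegetation and non-vegetation classes of
#' a cool temperate mountainous ecosystem, with ground-truth sample sizes of
#' 300 for thirteen classes, 165 for Hydrangea Shrub, 108 for Salix Shrub and
#' 107 for Tsuga ECF.  Trajectories encode the expected phenological
#' contrasts: deciduous classes have a summer NIR peak, evergreen conifers
#' stay green year-round, herbs have short sharp seasons, Water has low flat
#' NIR, and Barren-Built-up is flat mid reflectance.  Per-class spectral
#' offsets are small so classes overlap in any single index-month feature but
#' separate in combination.
#'
#' @param noise_sd per-band noise standard deviation passed to every profile.
#' @return list of 16 [class_profile()] objects, named by class.
#' @export
default_profiles <- function(noise_sd = 0.02) {
  shift <- function(spec, d) pmin(pmax(spec + d, 0), 1)
  defs <- list(
    ## name, n, greenness curve, background, vegetation spectrum
    list("Abies Evergreen Conifer Forest (ECF)", 300L,
         greenness_curve(0.72, 0.12, 7, 3.0), SPEC_SOIL,
         shift(SPEC_GREEN, c(0, -0.01, 0, -0.01, -0.03, -0.04))),
    list("Alnus Deciduous Broadleaf Forest (DBF)", 300L,
         greenness_curve(0.10, 0.85, 6.5, 2.2), SPEC_SOIL, SPEC_GREEN),
    list("Alpine Herb", 300L,
         greenness_curve(0.05, 0.80, 7.5, 1.2), SPEC_SOIL,
         shift(SPEC_GREEN, c(0, 0.01, 0.005, 0.01, -0.02, -0.02))),
    list("Alpine Shrub", 300L,
         greenness_curve(0.08, 0.75, 7.5, 1.8), SPEC_SOIL,
         shift(SPEC_GREEN, c(0, 0, 0, 0, -0.04, -0.05))),
    list("Barren-Built-up area", 300L,
         greenness_curve(0.05, 0.02, 7, 3.0), SPEC_SOIL, SPEC_SOIL),
    list("Cryptomeria-Chamaecyparis Evergreen Conifer Forest (ECF)", 300L,
         greenness_curve(0.78, 0.10, 7, 3.5), SPEC_SOIL,
         shift(SPEC_GREEN, c(-0.005, -0.015, -0.005, -0.02, -0.05, -0.06))),
    list("Fagus-Quercus Deciduous Broadleaf Forest (DBF)", 300L,
         greenness_curve(0.10, 0.88, 7.0, 2.0), SPEC_SOIL,
         shift(SPEC_GREEN, c(0, 0, 0, 0.01, 0.02, 0.03))),
    list("Hydrangea Shrub", 165L,
         greenness_curve(0.12, 0.72, 7.2, 2.0), SPEC_SOIL,
         shift(SPEC_GREEN, c(0, 0.005, 0, 0, -0.01, -0.02))),
    list("Miscanthus Herb", 300L,
         greenness_curve(0.08, 0.78, 8.0, 1.8), SPEC_SOIL,
         shift(SPEC_GREEN, c(0, 0.01, 0.01, 0.02, -0.01, 0))),
    list("Pinus Shrub", 300L,
         greenness_curve(0.65, 0.10, 7, 3.0), SPEC_SOIL,
         shift(SPEC_GREEN, c(0, -0.005, 0.005, -0.01, -0.06, -0.07))),
    list("Quercus Shrub", 300L,
         greenness_curve(0.12, 0.75, 7.0, 2.4), SPEC_SOIL,
         shift(SPEC_GREEN, c(0, 0, 0.005, 0, -0.02, -0.03))),
    list("Salix Shrub", 108L,
         greenness_curve(0.12, 0.78, 6.8, 2.4), SPEC_WET,
         shift(SPEC_GREEN, c(0, 0, 0, 0.005, -0.01, -0.01))),
    list("Sasa Shrub", 300L,
         greenness_curve(0.60, 0.20, 7, 2.8), SPEC_SOIL,
         shift(SPEC_GREEN, c(0, 0.01, 0, 0.01, -0.02, -0.03))),
    list("Tsuga Evergreen Conifer Forest (ECF)", 107L,
         greenness_curve(0.70, 0.10, 7, 3.2), SPEC_SOIL,
         shift(SPEC_GREEN, c(0.002, -0.012, 0.002, -0.015, -0.045, -0.05))),
    list("Water", 300L,
         greenness_curve(0, 0, 7, 3.0), SPEC_WATER, SPEC_WATER),
    list("Wetland Herb", 300L,
         greenness_curve(0.10, 0.70, 7.8, 1.6), SPEC_WET,
         shift(SPEC_GREEN, c(0, 0.005, 0, 0.01, -0.03, -0.04)))
  )
  sizes <- vapply(defs, function(d) d[[2]], integer(1))
  profiles <- lapply(defs, function(d)
    class_profile(d[[1]], mix_spectra(d[[3]], d[[4]], d[[5]]),
                  noise_sd = noise_sd, n_points = d[[2]]))
  names(profiles) <- vapply(profiles, `[[`, "", "class_name")
  profiles
}

#' Simulation configuration
#'
#' @param grid_size pixels per side of the square scene.
#' @param scenes_per_month number of scenes generated in each calendar month.
#' @param cloud_fraction probability in `[0, 1)` that a pixel observation is
#'   masked (cloud analog) in a given scene; masking is per pixel per scene.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param profiles list of [class_profile()]; defaults to
#'   [default_profiles()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(grid_size = 80L, scenes_per_month = 3L,
                       cloud_fraction = 0.2, seed = 1L,
                       profiles = default_profiles()) {
  stopifnot(grid_size >= 4, scenes_per_month >= 1,
            cloud_fraction >= 0, cloud_fraction < 1,
            length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "class_profile")))
  structure(list(grid_size = as.integer(grid_size),
                 scenes_per_month = as.integer(scenes_per_month),
                 cloud_fraction = cloud_fraction, seed = as.integer(seed),
                 profiles = profiles),
            class = "sim_config")
}

## Tile the grid into near-square rectangular regions, one (or more) per
## class; returns an integer matrix of class ids.
class_region_map <- function(grid_size, n_classes) {
  nr_reg <- max(1L, floor(sqrt(n_classes)))
  nc_reg <- ceiling(n_classes / nr_reg)
  row_reg <- pmin(((seq_len(grid_size) - 1L) %/%
                     ceiling(grid_size / nr_reg)) + 1L, nr_reg)
  col_reg <- pmin(((seq_len(grid_size) - 1L) %/%
                     ceiling(grid_size / nc_reg)) + 1L, nc_reg)
  reg <- outer(row_reg, col_reg, function(i, j) (i - 1L) * nc_reg + j)
  matrix(((reg - 1L) %% n_classes) + 1L, grid_size, grid_size)
}

#' Simulate dated six-band scenes and ground-truth points
#'
#' Generates `12 * scenes_per_month` scenes on a square grid tiled into
#' rectangular single-class regions.  Each pixel observation is the class's
#' monthly mean reflectance plus independent Gaussian noise per band,
#' truncated to `[0, 1]`; with probability `cloud_fraction` the whole pixel
#' observation is masked (`NA` in all six bands).  Ground-truth points are
#' distinct pixels drawn uniformly inside each class's region, with exactly
#' the per-class counts configured in the profiles.  Scene dates are evenly
#' spaced within each month; all scenes share one nominal year since the
#' compositing step only uses calendar-month membership.
#'
#' @param config a [sim_config()].
#' @return list with `scenes` (list of six-band [vc_raster()]s with dates),
#'   `points` (data.frame `class`, `x`, `y`; 0-based pixel coordinates) and
#'   `class_map` (integer matrix of class ids, with class names as the
#'   `classes` attribute).
#' @export
simulate_scenes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$grid_size
  profiles <- config$profiles
  ncl <- length(profiles)
  cmap <- class_region_map(g, ncl)
  counts <- tabulate(cmap, ncl)
  need <- vapply(profiles, `[[`, 0L, "n_points")
  if (any(counts < need))
    stop(sprintf("grid too small: class '%s' region has %d pixels but %d points requested",
                 profiles[[which(counts < need)[1]]]$class_name,
                 counts[which(counts < need)[1]], need[which(counts < need)[1]]))

  set.seed(config$seed)
  means <- lapply(profiles, `[[`, "monthly_means")   # each 12 x 6
  sds <- lapply(profiles, `[[`, "noise_sd")
  npix <- g * g
  cls_vec <- as.integer(t(cmap))   # row-major pixel order

  scenes <- vector("list", 12L * config$scenes_per_month)
  si <- 0L
  for (m in 1:12) {
    dim_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
    days <- round(seq(1, dim_days, length.out = config$scenes_per_month + 2L))
    days <- days[seq_len(config$scenes_per_month) + 1L]
    for (s in seq_len(config$scenes_per_month)) {
      mu <- t(vapply(means, function(mm) mm[m, ], numeric(6)))   # ncl x 6
      sdm <- t(vapply(sds, identity, numeric(6)))                # ncl x 6
      vals <- mu[cls_vec, , drop = FALSE] +
        matrix(rnorm(npix * 6L), npix, 6L) * sdm[cls_vec, , drop = FALSE]
      vals <- pmin(pmax(vals, 0), 1)
      if (config$cloud_fraction > 0) {
        cloud <- runif(npix) < config$cloud_fraction
        vals[cloud, ] <- NA_real_
      }
      colnames(vals) <- BAND_ROLES
      si <- si + 1L
      scenes[[si]] <- from_pixel_matrix(vals, g, g, bands = BAND_ROLES,
                                        date = as.Date(sprintf("2018-%02d-%02d",
                                                               m, days[s])))
    }
  }

  pts <- do.call(rbind, lapply(seq_len(ncl), function(k) {
    idx <- which(cls_vec == k)
    pick <- sort(sample(idx, profiles[[k]]$n_points))
    data.frame(class = profiles[[k]]$class_name,
               x = (pick - 1L) %% g,          # column, 0-based
               y = (pick - 1L) %/% g,         # row, 0-based
               stringsAsFactors = FALSE)
  }))
  rownames(pts) <- NULL
  attr(cmap, "classes") <- names(profiles)
  list(scenes = scenes, points = pts, class_map = cmap)
}
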