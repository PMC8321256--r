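# Shared fixtures: all synthetic, built in code at test time.

# Down-scaled 16-class world (same phenology profiles, fewer points) so a
# full pipeline run stays fast.
small_config <- function(seed = 1, grid_size = 40, scenes_per_month = 2,
                         cloud_fraction = 0.2, n_points = 25,
                         noise_sd = 0.02) {
  profiles <- lapply(default_profiles(noise_sd = noise_sd), function(p) {
    p$n_points <- as.integer(n_points)
    p
  })
  sim_config(grid_size = grid_size, scenes_per_month = scenes_per_month,
             cloud_fraction = cloud_fraction, seed = seed,
             profiles = profiles)
}

# Random 16-band "index stack" rasters with random masks and dates, for
# compositing tests.
random_stacks <- function(n_stacks, nrow = 4, ncol = 4, seed = 1,
                          na_frac = 0.3, months = NULL) {
  set.seed(seed)
  lapply(seq_len(n_stacks), function(i) {
    v <- array(runif(nrow * ncol * 16), c(nrow, ncol, 16))
    v[runif(length(v)) < na_frac] <- NA
    m <- if (is.null(months)) sample(1:12, 1) else months[i]
    vc_raster(v, bands = index_names(),
              date = as.Date(sprintf("2018-%02d-%02d", m, sample(1:28, 1))))
  })
}

# Perfectly separable labelled data: one distinct constant feature value per
# class (optionally plus pure-noise columns).
separable_data <- function(n_per_class = 10, n_classes = 4, n_noise = 0,
                           seed = 1) {
  set.seed(seed)
  lab <- rep(paste0("class", seq_len(n_classes)), each = n_per_class)
  X <- cbind(signal = rep(seq_len(n_classes) * 10, each = n_per_class))
  if (n_noise > 0)
    X <- cbind(X, matrix(rnorm(length(lab) * n_noise), ncol = n_noise,
                         dimnames = list(NULL,
                                         paste0("noise", seq_len(n_noise)))))
  labelled_features(X, lab)
}
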