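test_that("registry agrees with the single-expression oracle", {
  px <- random_band_pixels(1200, seed = 42)
  for (nm in index_names()) {
    got <- compute_index(nm, px[, "B"], px[, "G"], px[, "R"], px[, "RE1"],
                         px[, "RE3"], px[, "N"])
    want <- index_oracle[[nm]](px[, "B"], px[, "G"], px[, "R"], px[, "RE1"],
                               px[, "RE3"], px[, "N"])
    expect_true(all(abs(got - want) < 1e-12), label = nm)
  }
})

test_that("fixed example pixel matches the oracle on all 16 indices", {
  b <- 0.04; g <- 0.08; r <- 0.06; re1 <- 0.15; re3 <- 0.35; n <- 0.40
  for (nm in index_names())
    expect_equal(compute_index(nm, b, g, r, re1, re3, n),
                 index_oracle[[nm]](b, g, r, re1, re3, n), tolerance = 1e-14,
                 label = nm)
})

test_that("algebraic identities hold", {
  expect_equal(compute_index("NDVI", 0.1, 0.1, 0.3, 0.1, 0.1, 0.3), 0)
  ## MSAVI with N = R: discriminant is (2N+1)^2 exactly
  expect_equal(compute_index("MSAVI", 0.1, 0.1, 0.3, 0.1, 0.1, 0.3), 0)
  ## normalized differences bounded for strictly positive bands
  px <- random_band_pixels(500, seed = 9)
  for (nm in c("NDVI", "GNDVI", "GRVI", "RENDVI")) {
    v <- compute_index(nm, px[, 1], px[, 2], px[, 3], px[, 4], px[, 5],
                       px[, 6])
    expect_true(all(v >= -1 & v <= 1), label = nm)
  }
  ## MSAVI discriminant never negative on valid reflectance
  d <- (2 * px[, "N"] + 1)^2 - 8 * (px[, "N"] - px[, "R"])
  expect_true(all(d >= 0))
})

test_that("near-zero denominators mask only the affected index", {
  ## SIPI denominator N - R == 0, everything else finite
  v <- vapply(index_names(), function(nm)
    compute_index(nm, 0.04, 0.08, 0.3, 0.15, 0.35, 0.3), 0)
  expect_true(is.na(v["SIPI"]))
  expect_true(all(is.finite(v[setdiff(names(v), "SIPI")])))
})

test_that("compute_stack equals the per-pixel loop oracle and propagates masks", {
  set.seed(5)
  vals <- array(runif(6 * 6 * 6, 0.01, 0.9), c(6, 6, 6))
  vals[1, 1, ] <- NA                      # fully masked pixel
  vals[2, 2, 3] <- 1.5                    # valid: within [-0.1, 2]
  vals[3, 3, 2] <- 2.5                    # corrupt: outside [-0.1, 2]
  scene <- vc_raster(vals, bands = c("B", "G", "R", "RE1", "RE3", "N"),
                     date = as.Date("2018-07-01"))
  st <- compute_stack(scene)
  expect_equal(dim(st)[3], 16L)
  expect_identical(st$bands, index_names())
  m <- as_pixel_matrix(scene)
  sm <- as_pixel_matrix(st)
  for (p in seq_len(nrow(m))) {
    for (j in seq_along(index_names())) {
      bands <- m[p, ]
      want <- if (anyNA(bands) || any(bands < -0.1 | bands > 2))
        NA_real_
      else index_oracle[[index_names()[j]]](bands[1], bands[2], bands[3],
                                            bands[4], bands[5], bands[6])
      expect_equal(unname(sm[p, j]), unname(want), tolerance = 1e-12)
    }
  }
})

test_that("all-masked scenes yield fully masked stacks; missing roles error", {
  vals <- array(NA_real_, c(3, 3, 6))
  scene <- vc_raster(vals, bands = c("B", "G", "R", "RE1", "RE3", "N"))
  st <- compute_stack(scene)
  expect_true(all(is.na(st$values)))
  bad <- vc_raster(array(0.1, c(3, 3, 5)),
                   bands = c("B", "G", "R", "RE1", "RE3"))
  expect_error(compute_stack(bad), "missing band role.*N")
})
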