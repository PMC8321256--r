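test_that("monthly median matches the sort-based per-cell oracle exactly", {
  stacks <- random_stacks(8, nrow = 4, ncol = 4, seed = 11, na_frac = 0.4)
  comp <- monthly_median(stacks)
  expect_equal(dim(comp)[3], 192L)
  expect_identical(unname(as_pixel_matrix(comp)), composite_oracle(stacks))
})

test_that("simple composite cases", {
  ## one scene per month, no masks: composite equals the scenes
  stacks <- random_stacks(12, seed = 2, na_frac = 0, months = 1:12)
  comp <- monthly_median(stacks)
  m <- as_pixel_matrix(comp)
  for (mm in 1:12)
    expect_identical(unname(m[, (mm - 1) * 16 + 1:16]),
                     unname(as_pixel_matrix(stacks[[mm]])))
  ## odd-count median is the middle order statistic
  obs <- c(0.2, 0.9, 0.4)
  st <- lapply(obs, function(v)
    vc_raster(array(v, c(1, 1, 16)), bands = index_names(),
              date = as.Date("2018-03-10")))
  expect_equal(as_pixel_matrix(monthly_median(st))[1, "m03_NDVI"], 0.4,
               ignore_attr = TRUE)
})

test_that("composite is permutation-invariant and idempotent", {
  stacks <- random_stacks(9, seed = 3, na_frac = 0.3)
  comp <- monthly_median(stacks)
  set.seed(1)
  comp_shuf <- monthly_median(sample(stacks))
  expect_identical(comp$values, comp_shuf$values)

  ## idempotence: feed the composite back as 12 single-month stacks
  m <- as_pixel_matrix(comp)
  singles <- lapply(1:12, function(mm)
    from_pixel_matrix(m[, (mm - 1) * 16 + 1:16, drop = FALSE],
                      dim(comp)[1], dim(comp)[2], bands = index_names(),
                      date = as.Date(sprintf("2018-%02d-15", mm))))
  expect_identical(monthly_median(singles)$values, comp$values)
})

test_that("adding a fully masked observation changes nothing", {
  stacks <- random_stacks(6, seed = 8, na_frac = 0.2)
  comp <- monthly_median(stacks)
  blank <- vc_raster(array(NA_real_, c(4, 4, 16)), bands = index_names(),
                     date = as.Date("2018-05-20"))
  expect_identical(monthly_median(c(stacks, list(blank)))$values, comp$values)
})

test_that("mismatched grids are rejected with the offending stack named", {
  stacks <- random_stacks(2, seed = 1)
  stacks[[2]] <- vc_raster(array(0.5, c(5, 4, 16)), bands = index_names(),
                           date = as.Date("2018-02-02"))
  expect_error(monthly_median(stacks), "stack 2")
})

test_that("gap filling interpolates, extrapolates and reports drops", {
  ## build a 1-pixel composite directly
  m <- matrix(0.5, 1, 192, dimnames = list(NULL, composite_band_names()))
  ## index 1 (ARVI): months 1 and 3 valid at 0.2 / 0.6, month 2 missing
  m[1, "m01_ARVI"] <- 0.2; m[1, "m02_ARVI"] <- NA; m[1, "m03_ARVI"] <- 0.6
  ## index 2 (EVI): single valid month
  evi_cols <- grep("_EVI$", colnames(m))
  m[1, evi_cols] <- NA; m[1, "m06_EVI"] <- 0.33
  comp <- from_pixel_matrix(m, 1, 1, bands = composite_band_names())
  filled <- fill_gaps(comp)
  fm <- as_pixel_matrix(filled)
  expect_equal(fm[1, "m02_ARVI"], 0.4, ignore_attr = TRUE)
  expect_equal(unname(fm[1, evi_cols]), rep(0.33, 12))
  expect_false(anyNA(fm))
  expect_equal(attr(filled, "fill_count"), 12L)
  expect_false(any(attr(filled, "dropped")))

  ## identity on complete input
  full <- from_pixel_matrix(matrix(runif(192), 1), 1, 1,
                            bands = composite_band_names())
  expect_identical(as_pixel_matrix(fill_gaps(full)),
                   as_pixel_matrix(full))

  ## an index with zero valid months flags the pixel as dropped
  m2 <- m
  m2[1, grep("_GCI$", colnames(m2))] <- NA
  dropped <- fill_gaps(from_pixel_matrix(m2, 1, 1,
                                         bands = composite_band_names()))
  expect_true(attr(dropped, "dropped")[1])
})
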