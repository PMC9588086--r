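test_that("extract_profile averages the selected plane across the ROI", {
  # constant image -> constant raw profile
  im <- channel_image(matrix(0.4, 20, 30), pixel_size = 2)
  prof <- extract_profile(im)
  expect_equal(prof$intensities, rep(0.4, 30))
  expect_equal(prof$positions, (1:30 - 0.5) * 2)
  # grayscale luma equals the single plane
  expect_equal(extract_profile(im, channel = "luma")$intensities,
               prof$intensities)
  # blue-plane selection on RGB
  arr <- array(0, dim = c(5, 8, 3))
  arr[, , 3] <- matrix(seq(0, 1, length.out = 8), 5, 8, byrow = TRUE)
  prof_b <- extract_profile(channel_image(arr))
  expect_equal(prof_b$intensities, seq(0, 1, length.out = 8))
  # ROI errors
  expect_error(extract_profile(im, roi = list(rows = c(1, 50),
                                              cols = c(1, 10))), "bounds")
  expect_error(extract_profile(im, roi = list(rows = c(5, 2),
                                              cols = c(1, 10))), "roi")
})

test_that("extract_profile recovers the generator's analytic profile", {
  sim <- make_mixing_image(noise_sd = 0, seed = 1)
  prof <- normalize_profile(extract_profile(sim$image),
                            lo_ref = 0.08, hi_ref = 0.85)
  expect_equal(prof$intensities, sim$truth$intensities, tolerance = 1e-6)
  # monotone sigmoid shape
  expect_true(all(diff(prof$intensities) >= 0))
})

test_that("normalize_profile maps the reference levels to 0 and 1", {
  p <- intensity_profile(1:4, c(10, 10, 10, 10))
  expect_equal(normalize_profile(p, 5, 10)$intensities, rep(1, 4))
  expect_equal(normalize_profile(p, 10, 20)$intensities, rep(0, 4))
  mid <- intensity_profile(1:2, c(7.5, 7.5))
  expect_equal(normalize_profile(mid, 5, 10)$intensities, c(0.5, 0.5))
  expect_error(normalize_profile(p, 10, 10), "hi_ref")
})

test_that("AMI is the population coefficient of variation", {
  expect_identical(absolute_mixing_index(c(0, 0, 2, 2)), 1)
  expect_equal(absolute_mixing_index(c(0.4, 0.5, 0.6)), 0.16329932,
               tolerance = 1e-7)
  expect_identical(absolute_mixing_index(rep(0.7, 50)), 0)
  expect_error(absolute_mixing_index(c(0, 0, 0)), "zero")
  expect_error(absolute_mixing_index(0.5), "2 pixels")
})

test_that("AMI is scale-invariant and decreases under positive offsets", {
  for (seed in 1:20) {
    x <- withr::with_seed(seed, runif(40, 0.05, 1))
    a <- withr::with_seed(seed + 100, runif(1, 0.1, 10))
    expect_equal(absolute_mixing_index(a * x), absolute_mixing_index(x),
                 tolerance = 1e-12)
    expect_equal(absolute_mixing_index(x), ami_oracle(x), tolerance = 1e-12)
    expect_lt(absolute_mixing_index(x + 0.5), absolute_mixing_index(x))
  }
})

test_that("profile slope is the OLS slope and vanishes for mixed/symmetric data", {
  x <- seq(0, 150, by = 10)
  lin <- intensity_profile(x, 0.003 * x + 0.1)
  expect_equal(profile_slope(lin), 0.003, tolerance = 1e-12)
  expect_equal(profile_slope(intensity_profile(x, rep(0.5, length(x)))), 0)
  vee <- intensity_profile(seq(-5, 5), abs(seq(-5, 5)))
  expect_equal(profile_slope(vee), 0, tolerance = 1e-12)
  expect_equal(profile_slope(lin, abs = TRUE), 0.003, tolerance = 1e-12)
})

test_that("estimate_dilution interpolates between the 100% and 0% channels", {
  make_flat <- function(v) channel_image(matrix(v, 10, 10))
  imgs <- lapply(c(200, 150, 100, 0) / 255, make_flat)
  expect_equal(unname(estimate_dilution(imgs)), c(100, 75, 50, 0))
  # affine invariance: I -> a I + b leaves fractions unchanged
  imgs2 <- lapply(c(200, 150, 100, 0) / 255,
                  function(v) make_flat(0.8 * v + 0.1))
  expect_equal(estimate_dilution(imgs2), estimate_dilution(imgs))
  expect_error(estimate_dilution(lapply(rep(0.7, 4), make_flat)),
               "contrast")
})

test_that("a synthetic dilution ladder is recovered within noise", {
  fractions <- c(100, 51, 26, 0)
  imgs <- lapply(seq_along(fractions), function(k) {
    level <- 0.1 + (0.8 - 0.1) * fractions[k] / 100
    px <- withr::with_seed(k, {
      arr <- array(0.1, dim = c(24, 24, 3))
      arr[, , 3] <- level + rnorm(24 * 24, 0, 0.01)
      pmin(pmax(arr, 0), 1)
    })
    channel_image(px)
  })
  est <- estimate_dilution(imgs)
  expect_equal(unname(est), fractions, tolerance = 0.02)
  expect_equal(unname(est[c(1, 4)]), c(100, 0)) # by construction
})

test_that("mixing_vs_flowrate fits the linear flow dependence", {
  flows <- c(1, 1.5, 2, 5, 10)
  exact <- 0.004 * flows + 0.01
  fit <- mixing_vs_flowrate(flows, exact)
  expect_equal(fit$slope, 0.004, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.01, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_error(mixing_vs_flowrate(c(1, 2), c(0.1, 0.2)), "at least 3")
  expect_error(mixing_vs_flowrate(rep(2, 4), c(0.1, 0.2, 0.3, 0.4)),
               "all equal")
})
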