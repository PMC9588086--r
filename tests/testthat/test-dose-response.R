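test_that("viability is the live fraction in percent", {
  expect_equal(viability(90, 10), 90)
  expect_equal(viability(0, 37), 0)
  expect_equal(viability(158, 842), 15.8)
  # count-scaling invariance
  for (seed in 1:10) {
    counts <- withr::with_seed(seed, sample(0:500, 2))
    if (sum(counts) == 0) counts <- counts + 1
    a <- withr::with_seed(seed + 10, sample(1:9, 1))
    expect_equal(viability(a * counts[1], a * counts[2]),
                 viability(counts[1], counts[2]))
    expect_true(viability(counts[1], counts[2]) >= 0 &&
                  viability(counts[1], counts[2]) <= 100)
  }
  expect_error(viability(0, 0), "undefined")
})

test_that("zero-noise generated curves are recovered to 1e-6 relative", {
  sim <- make_dose_response(top = 90, bottom = 10, ec50 = 0.61, hill = 2,
                            doses = c(0, 0.25, 0.5, 1, 2, 4), noise_sd = 0)
  fit <- fit_dose_response(sim$data$dose, sim$data$viability)
  expect_equal(fit$top, 90, tolerance = 1e-6)
  expect_equal(fit$bottom, 10, tolerance = 1e-6)
  expect_equal(fit$ec50, 0.61, tolerance = 1e-6)
  expect_equal(fit$hill, 2, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # the model evaluates the zero dose exactly at the top plateau
  expect_equal(hill_viability(0, 90, 10, 0.61, 2), 90)
})

test_that("degenerate and mislabelled inputs are flagged, not silently fit", {
  flat <- c(50, 50, 50, 50)
  res <- tryCatch(fit_dose_response(c(0, 0.5, 1, 2), flat),
                  error = function(e) e)
  # either an explicit failure or an unidentifiable fit (R^2 undefined)
  expect_true(inherits(res, "error") || is.na(res$r2))
  expect_warning(
    fit_inc <- fit_dose_response(c(0, 0.5, 1, 2), c(20, 40, 60, 80)),
    "increases")
  expect_true(fit_inc$increasing_flag)
  expect_error(fit_dose_response(c(0, 1, 2), c(90, 50, 10)), "4 distinct")
})

test_that("EC50 is recovered within 15% at 5-point Gaussian noise", {
  errs <- vapply(1:30, function(seed) {
    sim <- make_dose_response(top = 90, bottom = 10, ec50 = 0.61, hill = 2,
                              doses = c(0, 0.25, 0.5, 1, 2, 4),
                              noise_sd = 5, seed = seed)
    fit <- fit_dose_response(sim$data$dose, sim$data$viability)
    abs(fit$ec50 - 0.61) / 0.61
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("published viability means give a mid-submillimolar EC50", {
  tabs <- printed_viability_tables()
  fit <- fit_dose_response(tabs$pegda_tmz$dose, tabs$pegda_tmz$viability)
  expect_gt(fit$ec50, 0.5)
  expect_lt(fit$ec50, 1.0)
  expect_gt(fit$r2, 0.95)
  # the adhesive-gel table sits higher on the viability scale throughout
  fit2 <- fit_dose_response(tabs$pegac_tmz$dose, tabs$pegac_tmz$viability)
  expect_true(all(tabs$pegac_tmz$viability > tabs$pegda_tmz$viability))
  expect_gt(fit2$top, fit$top)
})

test_that("ec50_comparison orders fits and reports potency ratios", {
  mk <- function(ec50) {
    sim <- make_dose_response(top = 95, bottom = 5, ec50 = ec50, hill = 2,
                              doses = c(0, 0.25, 0.5, 1, 2, 4, 8),
                              noise_sd = 0)
    fit_dose_response(sim$data$dose, sim$data$viability)
  }
  fits <- list(mk(1.8), mk(0.61))
  tab <- ec50_comparison(fits, c("degradable gel", "inert gel"))
  expect_equal(tab$label, c("inert gel", "degradable gel"))
  expect_equal(tab$ec50_ratio, c(1, 1.8 / 0.61), tolerance = 1e-4)
  same <- ec50_comparison(list(mk(1), mk(1)), c("a", "b"))
  expect_equal(same$ec50[1], same$ec50[2], tolerance = 1e-9)
  expect_equal(same$label, c("a", "b")) # stable order on ties
  expect_error(ec50_comparison(list(mk(1)), "a"), "at least two")
})

test_that("log-dose fitting mode agrees on the EC50 for positive doses", {
  sim <- make_dose_response(top = 90, bottom = 10, ec50 = 0.61, hill = 2,
                            doses = c(0.05, 0.2, 0.5, 1, 2, 4),
                            noise_sd = 0)
  fit_log <- fit_dose_response(sim$data$dose, sim$data$viability,
                               log_dose = TRUE)
  expect_equal(fit_log$ec50, 0.61, tolerance = 1e-4)
  expect_error(fit_dose_response(c(0, 0.5, 1, 2), c(90, 70, 40, 20),
                                 log_dose = TRUE), "positive")
})
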