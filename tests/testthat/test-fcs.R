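test_that("autocorrelation amplitude and limits follow the triplet model", {
  p10 <- fcs_params(10, 2.35e-5, 0.2, triplet_amp = 0)
  expect_equal(fcs_autocorrelation(0, p10), 0.1)
  pT <- fcs_params(10, 2.35e-5, 0.2, triplet_amp = 0.2, tau_t = 2e-6)
  expect_equal(fcs_autocorrelation(0, pT), 1 / (10 * (1 - 0.2)))
  # decay to zero at long lags, strictly decreasing throughout
  taus <- 10^seq(-7, 1, length.out = 200)
  g <- fcs_autocorrelation(taus, pT)
  expect_lt(g[length(g)], 1e-3)
  expect_true(all(diff(g) < 0))
  # matches the independently written model
  expect_equal(g, fcs_g_oracle(taus, 10, 2.35e-5, 0.2, 0.2, 2e-6),
               tolerance = 1e-12)
  expect_error(fcs_params(10, 2.35e-5, 0.2, triplet_amp = 1), "triplet_amp")
})

test_that("the axial-factor convention switch changes the model as documented", {
  pars <- fcs_params(5, 1e-4, 0.3)
  tau <- 1e-4
  g_sq <- fcs_autocorrelation(tau, pars, p_squared = TRUE)
  g_lit <- fcs_autocorrelation(tau, pars, p_squared = FALSE)
  expect_equal(g_sq * sqrt(1 + 0.3^2), g_lit * sqrt(1 + 0.3),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(g_sq, g_lit)))
})

test_that("normalization pins the first lag to 1 and cancels the amplitude", {
  lags <- 10^seq(-6, -2, length.out = 30)
  for (n in c(0.5, 2, 20)) {
    pars <- fcs_params(n, 2.35e-5, 0.2, 0.1, 2e-6)
    norm <- normalize_curve(fcs_curve(lags, fcs_autocorrelation(lags, pars)))
    expect_equal(norm$g[1], 1)
    if (n != 0.5) expect_equal(norm$g, ref_norm, tolerance = 1e-12)
    ref_norm <- norm$g
  }
  const <- fcs_curve(lags, rep(0.25, 30))
  expect_equal(normalize_curve(const)$g, rep(1, 30))
})

test_that("noiseless curves are recovered to 0.1% in all free parameters", {
  truth <- fcs_params(2, 2.35e-5, 0.2, triplet_amp = 0.15, tau_t = 2e-6)
  sim <- make_fcs_curve(truth, noise_frac = 0, seed = 1)
  fit <- fit_fcs(sim$curve, init = fcs_initial_guess(sim$curve, p = 0.2))
  expect_equal(fit$params$n_particles, 2, tolerance = 1e-3)
  expect_equal(fit$params$tau_d, 2.35e-5, tolerance = 1e-3)
  expect_equal(fit$params$triplet_amp, 0.15, tolerance = 1e-3)
  expect_equal(fit$params$tau_t, 2e-6, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$std_errors[setdiff(names(fit$std_errors),
                                                   fit$fixed)])))
})

test_that("a triplet-free curve fits identically with the triplet fixed off", {
  truth <- fcs_params(4, 5e-5, 0.25, triplet_amp = 0)
  sim <- make_fcs_curve(truth, noise_frac = 0, seed = 1)
  init <- fcs_params(3, 1e-4, 0.25, triplet_amp = 0, tau_t = 1e-6)
  fit_pure <- fit_fcs(sim$curve, init = init,
                      fixed = c("p", "triplet_amp", "tau_t"))
  fit_full <- fit_fcs(sim$curve, init = fcs_params(3, 1e-4, 0.25, 0.05,
                                                   1e-6),
                      fixed = "p")
  expect_equal(fit_pure$params$tau_d, 5e-5, tolerance = 1e-6)
  expect_equal(fit_full$params$tau_d, fit_pure$params$tau_d,
               tolerance = 1e-4)
})

test_that("fit_fcs validates its inputs", {
  lags <- 10^seq(-6, -2, length.out = 30)
  g <- fcs_autocorrelation(lags, fcs_params(2, 2.35e-5, 0.2))
  expect_error(fit_fcs(fcs_curve(lags[1:5], g[1:5])), "at least 10")
  narrow <- seq(1e-5, 5e-5, length.out = 20)
  expect_error(fit_fcs(fcs_curve(narrow,
                                 fcs_autocorrelation(narrow,
                                                     fcs_params(2, 2.35e-5,
                                                                0.2)))),
               "decades")
  expect_error(fit_fcs(fcs_curve(lags, g), fixed = "bananas"), "unknown")
})

test_that("tau_d is recovered within 5% under 2% multiplicative noise", {
  truth <- fcs_params(2, 2.35e-5, 0.2, triplet_amp = 0.15, tau_t = 2e-6)
  errs <- vapply(1:20, function(seed) {
    sim <- make_fcs_curve(truth, noise_frac = 0.02, seed = seed)
    fit <- fit_fcs(sim$curve,
                   init = fcs_initial_guess(sim$curve, p = 0.2))
    abs(fit$params$tau_d - truth$tau_d) / truth$tau_d
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("diffusivity and calibration invert each other exactly", {
  inst <- fcs_instrument(r0 = 2e-7, z0 = 1e-6)
  expect_equal(inst$p, 0.2)
  expect_equal(diffusivity_from_tau(inst, 2.35e-5), 4.2553191e-10,
               tolerance = 1e-7)
  expect_equal(diffusivity_from_tau(2 * 2e-7, 2.35e-5),
               4 * diffusivity_from_tau(2e-7, 2.35e-5))
  # round trips to machine precision
  d <- 4.26e-10; tau <- 2.35e-5
  expect_equal(diffusivity_from_tau(calibrate_confocal_volume(d, tau), tau),
               d, tolerance = 1e-15)
  expect_equal(calibrate_confocal_volume(4 * d, tau),
               2 * calibrate_confocal_volume(d, tau), tolerance = 1e-15)
  expect_error(diffusivity_from_tau(2e-7, 0), "tau_d")
})
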