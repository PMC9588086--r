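#' Triplet-model FCS parameters
#'
#' Parameters of the single-component 3-D diffusion autocorrelation with a
#' triplet (dark-state) term: mean particle number in the focal volume,
#' diffusion time, the instrumental aspect constant `p = r0 / z0`, the
#' triplet amplitude and the triplet lifetime.
#'
#' @param n_particles Mean number of fluorescent particles in the focal
#'   volume, > 0.
#' @param tau_d Diffusion time, s, > 0.
#' @param p Instrumental constant `r0 / z0`, > 0.
#' @param triplet_amp Triplet amplitude in [0, 1).
#' @param tau_t Triplet lifetime, s, > 0.
#' @return An object of class `"fcs_params"`.
#' @export
fcs_params <- function(n_particles, tau_d, p,
                       triplet_amp = 0, tau_t = 1e-6) {
  check_scalar(n_particles, "n_particles", positive = TRUE)
  check_scalar(tau_d, "tau_d", positive = TRUE)
  check_scalar(p, "p", positive = TRUE)
  check_scalar(triplet_amp, "triplet_amp", non_negative = TRUE)
  if (triplet_amp >= 1) {
    stop("`triplet_amp` must be < 1 (the triplet factor is singular at 1)",
         call. = FALSE)
  }
  check_scalar(tau_t, "tau_t", positive = TRUE)
  structure(list(n_particles = n_particles, tau_d = tau_d, p = p,
                 triplet_amp = triplet_amp, tau_t = tau_t),
            class = "fcs_params")
}

#' FCS instrument geometry
#'
#' Focal-spot radius and axial length of the confocal detection volume;
#' their ratio is the aspect constant `p` of the diffusion model.
#'
#' @param r0 Focal (lateral) radius, m, > 0.
#' @param z0 Axial half-length, m, > 0.
#' @return An object of class `"fcs_instrument"` with fields `r0`, `z0`,
#'   `p = r0 / z0`.
#' @export
fcs_instrument <- function(r0, z0) {
  check_scalar(r0, "r0", positive = TRUE)
  check_scalar(z0, "z0", positive = TRUE)
  structure(list(r0 = r0, z0 = z0, p = r0 / z0), class = "fcs_instrument")
}

#' An FCS autocorrelation curve
#'
#' @param lags Strictly increasing lag times, s, all > 0.
#' @param g Correlation amplitudes `G(tau)`, same length.
#' @return An object of class `"fcs_curve"`.
#' @export
fcs_curve <- function(lags, g) {
  check_numeric_vector(lags, "lags")
  check_numeric_vector(g, "g")
  if (length(lags) != length(g)) {
    stop("`lags` and `g` must have equal length", call. = FALSE)
  }
  if (any(lags <= 0) || any(diff(lags) <= 0)) {
    stop("`lags` must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(lags = lags, g = g), class = "fcs_curve")
}

#' Triplet-model autocorrelation function
#'
#' Single-component 3-D Gaussian diffusion with a triplet term:
#' \deqn{G(\tau) = \frac{1}{N} \frac{1}{1 + \tau/\tau_D}
#'   \frac{1}{\sqrt{1 + p^2 \tau/\tau_D}}
#'   \left(1 + \frac{T}{1 - T} e^{-\tau/\tau_T}\right).}
#' `p_squared = FALSE` selects a variant with `p` (not `p^2`) multiplying
#' `tau/tau_D` in the axial factor; the default is the standard `p^2` form
#' (see the methods vignette for why both are exposed).
#'
#' @param tau Lag times, s, >= 0 (vectorized).
#' @param params An [fcs_params()].
#' @param p_squared Use the standard `p^2` axial factor? Default `TRUE`.
#' @return `G(tau)`, dimensionless. At `tau = 0` this is
#'   `1 / (N (1 - T))`.
#' @export
fcs_autocorrelation <- function(tau, params, p_squared = TRUE) {
  stopifnot(inherits(params, "fcs_params"))
  check_numeric_vector(tau, "tau", non_negative = TRUE)
  fcs_model(tau, params$n_particles, params$tau_d, params$p,
            params$triplet_amp, params$tau_t, p_squared)
}

# Bare numeric kernel shared by fcs_autocorrelation() and fit_fcs().
fcs_model <- function(tau, n, tau_d, p, trip, tau_t, p_squared = TRUE) {
  x <- tau / tau_d
  axial <- if (p_squared) 1 + p^2 * x else 1 + p * x
  g <- (1 / n) / (1 + x) / sqrt(axial)
  if (trip > 0) g <- g * (1 + trip / (1 - trip) * exp(-tau / tau_t))
  g
}

#' Normalize an autocorrelation curve to its first lag
#'
#' Divides every value by `G` at the initial time point, so the first
#' normalized value is 1 and the particle-number amplitude `1/N` cancels.
#'
#' @param curve An [fcs_curve()].
#' @return A normalized [fcs_curve()].
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "fcs_curve"))
  g0 <- curve$g[1]
  if (g0 == 0) stop("G at the first lag is zero; cannot normalize",
                    call. = FALSE)
  fcs_curve(curve$lags, curve$g / g0)
}

#' Data-driven starting values for a triplet-model fit
#'
#' Amplitude from the first correlation value (`N ~ 1/G(tau_0)`), diffusion
#' time from the lag where the curve has decayed to half its initial value,
#' and mild triplet defaults.
#'
#' @param curve An [fcs_curve()].
#' @param p Instrumental constant to carry into the guess.
#' @return An [fcs_params()].
#' @export
fcs_initial_guess <- function(curve, p = 0.2) {
  stopifnot(inherits(curve, "fcs_curve"))
  g0 <- max(curve$g[1], .Machine$double.eps)
  half_idx <- which.min(abs(curve$g - g0 / 2))
  fcs_params(n_particles = 1 / g0,
             tau_d = curve$lags[half_idx],
             p = p,
             triplet_amp = 0.05,
             tau_t = curve$lags[1])
}

#' Fit the triplet model to an autocorrelation curve
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) of the
#' triplet-model autocorrelation against a measured curve. Parameters named
#' in `fixed` are held at their `init` values (typically `p`, fixed from
#' confocal-volume calibration). Box bounds enforce the parameter
#' invariants (positivity, triplet amplitude in [0, 1)) rather than
#' penalty terms.
#'
#' @param curve An [fcs_curve()] with >= 10 points spanning at least two
#'   decades of lag.
#' @param init Starting [fcs_params()]; default [fcs_initial_guess()].
#' @param fixed Character vector of parameter names to hold fixed; any of
#'   `"n_particles"`, `"tau_d"`, `"p"`, `"triplet_amp"`, `"tau_t"`.
#'   Default `"p"`.
#' @param p_squared Axial-factor convention, see [fcs_autocorrelation()].
#' @param weights `"none"` (default, unweighted) or `"inverse_g2"`
#'   (relative, 1/G^2) residual weighting.
#' @param max_iter Iteration budget for the optimizer.
#' @return An object of class `"fcs_fit"`: a list with `params`
#'   ([fcs_params()]), `std_errors` (named, NA for fixed parameters),
#'   `residual_norm`, `converged`, `iterations`, `fixed`.
#' @export
fit_fcs <- function(curve, init = NULL, fixed = "p", p_squared = TRUE,
                    weights = c("none", "inverse_g2"), max_iter = 200L) {
  stopifnot(inherits(curve, "fcs_curve"))
  weights <- match.arg(weights)
  if (length(curve$lags) < 10L) {
    stop("need at least 10 correlation points", call. = FALSE)
  }
  if (max(curve$lags) / min(curve$lags) < 100) {
    stop("lags must span at least two decades", call. = FALSE)
  }
  if (is.null(init)) init <- fcs_initial_guess(curve)
  stopifnot(inherits(init, "fcs_params"))
  par_names <- c("n_particles", "tau_d", "p", "triplet_amp", "tau_t")
  bad <- setdiff(fixed, par_names)
  if (length(bad)) {
    stop(sprintf("unknown parameter(s) in `fixed`: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  free <- setdiff(par_names, fixed)
  if (length(free) == 0L) stop("no free parameters to fit", call. = FALSE)

  lower <- c(n_particles = 1e-12, tau_d = 1e-12, p = 1e-12,
             triplet_amp = 0, tau_t = 1e-12)
  upper <- c(n_particles = Inf, tau_d = Inf, p = Inf,
             triplet_amp = 1 - 1e-9, tau_t = Inf)
  start <- unlist(init[par_names])[free]
  w <- if (weights == "inverse_g2") 1 / pmax(curve$g, .Machine$double.eps)
       else rep(1, length(curve$g))

  residual_fn <- function(par) {
    full <- unlist(init[par_names])
    full[free] <- par
    w * (fcs_model(curve$lags, full["n_particles"], full["tau_d"],
                   full["p"], full["triplet_amp"], full["tau_t"],
                   p_squared) - curve$g)
  }
  fit <- minpack.lm::nls.lm(par = start, fn = residual_fn,
                            lower = lower[free], upper = upper[free],
                            control = minpack.lm::nls.lm.control(
                              maxiter = as.integer(max_iter)))
  converged <- fit$info %in% 1:4
  full <- unlist(init[par_names])
  full[free] <- fit$par
  params <- fcs_params(full[["n_particles"]], full[["tau_d"]], full[["p"]],
                       full[["triplet_amp"]], full[["tau_t"]])
  se <- stats::setNames(rep(NA_real_, 5L), par_names)
  se_free <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                      error = function(e) rep(NA_real_, length(free)))
  se[free] <- se_free
  out <- structure(list(params = params, std_errors = se,
                        residual_norm = sqrt(fit$deviance),
                        converged = converged,
                        iterations = fit$niter, fixed = fixed),
                   class = "fcs_fit")
  if (!converged) {
    stop(paste0("FCS fit did not converge (info = ", fit$info, ", ",
                fit$message, "); residual norm ",
                format(out$residual_norm)), call. = FALSE)
  }
  out
}

#' @export
print.fcs_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<fcs_fit> N = %.4g, tau_d = %.4g s, p = %.4g, ",
                     "T = %.4g, tau_t = %.4g s\n"),
              p$n_particles, p$tau_d, p$p, p$triplet_amp, p$tau_t))
  cat(sprintf("  residual norm %.4g after %d iterations (fixed: %s)\n",
              x$residual_norm, x$iterations,
              if (length(x$fixed)) paste(x$fixed, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Diffusion coefficient from a fitted diffusion time
#'
#' `D = r0^2 / (4 tau_d)` for a calibrated focal radius `r0`.
#'
#' @param instrument An [fcs_instrument()], or a numeric focal radius `r0`
#'   in metres.
#' @param tau_d Fitted diffusion time, s, > 0.
#' @return Diffusion coefficient, m^2/s.
#' @export
diffusivity_from_tau <- function(instrument, tau_d) {
  r0 <- if (inherits(instrument, "fcs_instrument")) instrument$r0
        else instrument
  check_scalar(r0, "r0", positive = TRUE)
  check_scalar(tau_d, "tau_d", positive = TRUE)
  r0^2 / (4 * tau_d)
}

#' Calibrate the confocal focal radius from a reference dye
#'
#' Inverts `D = r0^2 / (4 tau_d)`: given the known diffusivity of a
#' calibration dye and its fitted diffusion time, returns the focal radius
#' `r0 = sqrt(4 D tau_d)`.
#'
#' @param known_d Known diffusivity of the calibration dye, m^2/s, > 0.
#' @param fitted_tau_d Fitted diffusion time of the dye, s, > 0.
#' @return Focal radius r0, m.
#' @export
calibrate_confocal_volume <- function(known_d, fitted_tau_d) {
  check_scalar(known_d, "known_d", positive = TRUE)
  check_scalar(fitted_tau_d, "fitted_tau_d", positive = TRUE)
  sqrt(4 * known_d * fitted_tau_d)
}
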