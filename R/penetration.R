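#' Fickian semi-infinite penetration state
#'
#' Boundary concentration, diffusivity, depth and time for the 1-D
#' constant-surface-concentration solution of Fick's second law,
#' `c(x, t) = c0 (1 - erf(x / (2 sqrt(D t))))`.
#'
#' @param c0 Boundary (surface) concentration, any concentration unit.
#' @param diffusivity Diffusion coefficient in the medium, m^2/s, > 0.
#' @param depth Depth into the medium, m, >= 0.
#' @param time Elapsed time, s, >= 0.
#' @return An object of class `"penetration_spec"`.
#' @export
penetration_spec <- function(c0, diffusivity, depth, time) {
  check_scalar(c0, "c0", non_negative = TRUE)
  check_scalar(diffusivity, "diffusivity", positive = TRUE)
  check_scalar(depth, "depth", non_negative = TRUE)
  check_scalar(time, "time", non_negative = TRUE)
  structure(list(c0 = c0, diffusivity = diffusivity,
                 depth = depth, time = time),
            class = "penetration_spec")
}

# Vectorized erf kernel; t = 0 with x > 0 returns the limit 0.
penetration_kernel <- function(x, t, c0, d) {
  arg <- ifelse(t > 0, x / (2 * sqrt(d * t)), ifelse(x > 0, Inf, 0))
  c0 * (1 - erf(arg))
}

#' Concentration at a depth and time under constant surface concentration
#'
#' Evaluates the semi-infinite Fickian solution
#' `c(x, t) = c0 (1 - erf(x / (2 sqrt(D t))))`; `c(0, t) = c0` and
#' `c(x, 0) = 0` for `x > 0` (taken as the limit, not an error).
#'
#' @param spec A [penetration_spec()].
#' @return Concentration in the units of `c0`.
#' @examples
#' # 2 mM drug after 48 h at 250 um depth in a gel with D = 2.55e-10 m^2/s
#' concentration_at(penetration_spec(2, 2.55e-10, 250e-6, 48 * 3600))
#' @export
concentration_at <- function(spec) {
  stopifnot(inherits(spec, "penetration_spec"))
  penetration_kernel(spec$depth, spec$time, spec$c0, spec$diffusivity)
}

#' Concentration matrix over depth and time grids
#'
#' Elementwise [concentration_at()] on the outer product of a depth grid
#' and a time grid.
#'
#' @param c0 Boundary concentration.
#' @param diffusivity Diffusion coefficient, m^2/s.
#' @param depths Non-empty grid of depths, m, >= 0.
#' @param times Non-empty grid of times, s, >= 0.
#' @return Matrix of concentrations, rows = depths, columns = times, with
#'   dimnames from the grids.
#' @export
penetration_profile <- function(c0, diffusivity, depths, times) {
  check_scalar(c0, "c0", non_negative = TRUE)
  check_scalar(diffusivity, "diffusivity", positive = TRUE)
  check_numeric_vector(depths, "depths", non_negative = TRUE)
  check_numeric_vector(times, "times", non_negative = TRUE)
  out <- outer(depths, times,
               function(x, t) penetration_kernel(x, t, c0, diffusivity))
  dimnames(out) <- list(depth_m = format(depths, trim = TRUE),
                        time_s = format(times, trim = TRUE))
  out
}

#' Time for the penetrating front to reach a target concentration
#'
#' Solves `c0 (1 - erf(x / (2 sqrt(D t)))) = c_target` for `t` at a fixed
#' depth `x`. The concentration is strictly increasing in `t`, so the root
#' is unique; it is found by sign-change bracketing on `log(t)` around the
#' diffusive time scale `x^2 / (4 D)`, to ~1e-9 relative tolerance.
#'
#' @param c_target Target concentration, strictly between 0 and `c0`.
#' @param x Depth, m, > 0.
#' @param diffusivity Diffusion coefficient, m^2/s, > 0.
#' @param c0 Boundary concentration, > 0.
#' @return Time in seconds.
#' @examples
#' # time for 2 mM surface drug to exceed 1.9 mM at 250 um in gel
#' time_to_threshold(1.9, 250e-6, 2.55e-10, 2)
#' @export
time_to_threshold <- function(c_target, x, diffusivity, c0) {
  check_scalar(c_target, "c_target", positive = TRUE)
  check_scalar(x, "x", positive = TRUE)
  check_scalar(diffusivity, "diffusivity", positive = TRUE)
  check_scalar(c0, "c0", positive = TRUE)
  if (c_target >= c0) {
    stop("`c_target` must be below `c0`: the boundary value is approached ",
         "only as t -> Inf", call. = FALSE)
  }
  f <- function(logt) {
    penetration_kernel(x, exp(logt), c0, diffusivity) - c_target
  }
  # diffusive scale; expand the bracket in decades until the sign changes
  t0 <- x^2 / (4 * diffusivity)
  lo <- log(t0) - log(10)
  hi <- log(t0) + log(10)
  while (f(lo) > 0) lo <- lo - log(10)
  while (f(hi) < 0) hi <- hi + log(10)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  exp(root$root)
}
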