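#' Cell viability from live/dead counts
#'
#' `viability = 100 * N_live / (N_live + N_dead)` in percent. Vectorized;
#' invariant under scaling both counts by the same factor.
#'
#' @param n_live Live-cell counts, >= 0.
#' @param n_dead Dead-cell counts, >= 0.
#' @return Viability in percent, in [0, 100].
#' @examples
#' viability(90, 10) # 90
#' @export
viability <- function(n_live, n_dead) {
  check_numeric_vector(n_live, "n_live", non_negative = TRUE)
  check_numeric_vector(n_dead, "n_dead", non_negative = TRUE)
  total <- n_live + n_dead
  if (any(total == 0)) {
    stop("viability undefined: no cells counted (n_live + n_dead == 0)",
         call. = FALSE)
  }
  100 * n_live / total
}

#' Hill-type viability model on linear concentration
#'
#' `V(c) = bottom + (top - bottom) / (1 + (c / ec50)^hill)`; at `c = 0`
#' this is exactly `top` (the untreated control), decreasing towards
#' `bottom` at saturating dose. This is the sigmoid used by
#' [fit_dose_response()] and [make_dose_response()].
#'
#' @param conc Doses, >= 0 (vectorized).
#' @param top,bottom Upper and lower viability plateaus, percent.
#' @param ec50 Dose at the half-effect midpoint, > 0.
#' @param hill Hill coefficient, > 0.
#' @return Viabilities, percent.
#' @export
hill_viability <- function(conc, top, bottom, ec50, hill) {
  bottom + (top - bottom) / (1 + (conc / ec50)^hill)
}

#' Fit a sigmoidal dose-response curve and extract the EC50
#'
#' Levenberg-Marquardt least squares (via \pkg{minpack.lm}) of
#' [hill_viability()] against viability-vs-dose data on the linear
#' concentration scale (a true zero dose is handled exactly:
#' `V(0) = top`). Default box constraints keep the plateaus physical
#' (`0 <= bottom`, `top <= 100`). Set `log_dose = TRUE` to fit on
#' `log10(c)` instead (requires all doses > 0).
#'
#' @param conc Doses (mM or uM), >= 0, at least 4 distinct levels.
#' @param viab Viabilities, percent, same length.
#' @param lower,upper Named bounds for `top`, `bottom`, `ec50`, `hill`.
#' @param start Optional named starting values; defaults are data-driven.
#' @param log_dose Fit a 4PL on the log10 dose scale? Default `FALSE`.
#' @return An object of class `"dose_response_fit"`: list with `ec50`,
#'   `hill`, `top`, `bottom`, `r2`, `fitted`, `data`,
#'   `increasing_flag` (`TRUE` when viability trends upward with dose,
#'   which usually signals mislabelled data), and `convergence info`.
#' @examples
#' d <- make_dose_response(top = 90, bottom = 10, ec50 = 0.61, hill = 2,
#'                         doses = c(0, 0.25, 0.5, 1, 2, 4), seed = 1)
#' fit_dose_response(d$data$dose, d$data$viability)
#' @export
fit_dose_response <- function(conc, viab,
                              lower = c(top = 0, bottom = 0,
                                        ec50 = 1e-12, hill = 1e-3),
                              upper = c(top = 100, bottom = 100,
                                        ec50 = Inf, hill = Inf),
                              start = NULL, log_dose = FALSE) {
  check_numeric_vector(conc, "conc", non_negative = TRUE)
  check_numeric_vector(viab, "viab")
  if (length(conc) != length(viab)) {
    stop("`conc` and `viab` must have equal length", call. = FALSE)
  }
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct dose levels for a 4-parameter fit",
         call. = FALSE)
  }
  if (log_dose && any(conc <= 0)) {
    stop("`log_dose = TRUE` requires strictly positive doses", call. = FALSE)
  }
  # constant viability makes the correlation undefined; that case is
  # caught below as an unidentifiable fit, not a direction flag
  increasing <- suppressWarnings(stats::cor(conc, viab)) > 0
  if (isTRUE(increasing)) {
    warning("viability increases with dose; check dose/viability columns",
            call. = FALSE)
  }
  if (is.null(start)) {
    mid <- (max(viab) + min(viab)) / 2
    pos <- conc[conc > 0]
    start <- c(top = max(viab), bottom = min(viab),
               ec50 = if (length(pos)) pos[which.min(abs(viab[conc > 0] - mid))]
                      else stats::median(conc),
               hill = 1)
    start["ec50"] <- max(start["ec50"], lower["ec50"] * 10)
  }
  model <- if (log_dose) {
    function(cc, top, bottom, ec50, hill) {
      bottom + (top - bottom) / (1 + 10^(hill * (log10(cc) - log10(ec50))))
    }
  } else hill_viability
  fit <- tryCatch(
    minpack.lm::nlsLM(
      viab ~ model(conc, top, bottom, ec50, hill),
      start = as.list(start),
      lower = lower[c("top", "bottom", "ec50", "hill")],
      upper = upper[c("top", "bottom", "ec50", "hill")],
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf("dose-response fit failed: %s", conditionMessage(e)),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  fitted_v <- model(conc, cf[["top"]], cf[["bottom"]], cf[["ec50"]],
                    cf[["hill"]])
  ss_res <- sum((viab - fitted_v)^2)
  ss_tot <- sum((viab - mean(viab))^2)
  structure(list(ec50 = cf[["ec50"]], hill = cf[["hill"]],
                 top = cf[["top"]], bottom = cf[["bottom"]],
                 r2 = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
                 fitted = fitted_v,
                 data = data.frame(dose = conc, viability = viab),
                 increasing_flag = isTRUE(increasing),
                 log_dose = log_dose),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("<dose_response_fit> EC50 = %.4g, hill = %.3g, ",
                     "top = %.3g%%, bottom = %.3g%%, R^2 = %.4g\n"),
              x$ec50, x$hill, x$top, x$bottom, x$r2))
  if (x$increasing_flag) cat("  warning: viability increases with dose\n")
  invisible(x)
}

#' Compare EC50s across conditions
#'
#' Tabulates a set of dose-response fits, sorted by EC50, with each EC50's
#' ratio to the most potent (smallest) one.
#'
#' @param fits List of at least two `"dose_response_fit"` objects.
#' @param labels Character labels, one per fit.
#' @return A data.frame with columns `label`, `ec50`, `hill`, `r2`,
#'   `ec50_ratio` (relative to the smallest EC50), ordered by `ec50`.
#' @export
ec50_comparison <- function(fits, labels) {
  if (!is.list(fits) || length(fits) < 2L) {
    stop("need at least two fits to compare", call. = FALSE)
  }
  ok <- vapply(fits, inherits, logical(1), "dose_response_fit")
  if (!all(ok)) stop("all elements must be dose_response_fit objects",
                     call. = FALSE)
  if (length(labels) != length(fits)) {
    stop("`labels` must match `fits` in length", call. = FALSE)
  }
  tab <- data.frame(label = as.character(labels),
                    ec50 = vapply(fits, `[[`, numeric(1), "ec50"),
                    hill = vapply(fits, `[[`, numeric(1), "hill"),
                    r2 = vapply(fits, `[[`, numeric(1), "r2"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$ec50), , drop = FALSE]
  tab$ec50_ratio <- tab$ec50 / tab$ec50[1]
  rownames(tab) <- NULL
  tab
}
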