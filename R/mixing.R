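#' Channel image container
#'
#' Wraps a micrograph of a microfluidic channel: a grayscale matrix or an
#' RGB array (`height x width x 3`) of non-negative intensities, the pixel
#' size in um/pixel, and optionally a rectangular region of interest
#' spanning the channel width.
#'
#' ROI convention: 1-based inclusive row/column index ranges,
#' `list(rows = c(first, last), cols = c(first, last))`. Columns run across
#' the channel width; rows run along the flow direction.
#'
#' @param pixels Numeric matrix or `h x w x 3` array, finite and >= 0.
#' @param pixel_size Pixel size, um/pixel.
#' @param roi Optional ROI list; defaults to the full frame.
#' @return An object of class `"channel_image"`.
#' @export
channel_image <- function(pixels, pixel_size = 1, roi = NULL) {
  if (!is.numeric(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("`pixels` must be finite and non-negative", call. = FALSE)
  }
  nd <- length(dim(pixels))
  if (is.null(dim(pixels)) || !(nd == 2L || (nd == 3L && dim(pixels)[3] == 3L))) {
    stop("`pixels` must be a matrix or an h x w x 3 array", call. = FALSE)
  }
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (is.null(roi)) roi <- list(rows = c(1L, h), cols = c(1L, w))
  validate_roi(roi, h, w)
  structure(list(pixels = pixels, pixel_size = pixel_size, roi = roi),
            class = "channel_image")
}

validate_roi <- function(roi, h, w) {
  if (!is.list(roi) || !all(c("rows", "cols") %in% names(roi))) {
    stop("`roi` must be list(rows = c(first, last), cols = c(first, last))",
         call. = FALSE)
  }
  r <- roi$rows; cl <- roi$cols
  if (length(r) != 2L || length(cl) != 2L || r[1] > r[2] || cl[1] > cl[2]) {
    stop("empty or malformed roi", call. = FALSE)
  }
  if (r[1] < 1 || r[2] > h || cl[1] < 1 || cl[2] > w) {
    stop(sprintf("roi outside image bounds (%d x %d)", h, w), call. = FALSE)
  }
  invisible(roi)
}

#' Cross-width intensity profile
#'
#' Ordered positions across the channel width (um) with intensities, the
#' input to [absolute_mixing_index()] and [profile_slope()]. Intensities
#' are expected in [0, 1] after [normalize_profile()] but any non-negative
#' values are accepted (raw profiles).
#'
#' @param positions Strictly increasing distances across the width, um.
#' @param intensities Intensities, same length as `positions`.
#' @return An object of class `"intensity_profile"` with fields
#'   `positions`, `intensities`, `n`.
#' @export
intensity_profile <- function(positions, intensities) {
  check_numeric_vector(positions, "positions")
  check_numeric_vector(intensities, "intensities")
  if (length(positions) != length(intensities)) {
    stop("`positions` and `intensities` must have equal length", call. = FALSE)
  }
  if (any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  structure(list(positions = positions, intensities = intensities,
                 n = length(intensities)),
            class = "intensity_profile")
}

# Pull a single color plane out of a channel_image.
select_plane <- function(pixels, channel = c("blue", "green", "red", "luma")) {
  channel <- match.arg(channel)
  if (length(dim(pixels)) == 2L) return(pixels)
  switch(channel,
         red = pixels[, , 1],
         green = pixels[, , 2],
         blue = pixels[, , 3],
         luma = 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] +
           0.114 * pixels[, , 3])
}

#' Extract a cross-width intensity profile from a channel image
#'
#' Averages the selected color plane over the ROI rows for each ROI column,
#' giving one intensity per position across the channel width (the
#' equivalent of ImageJ's "Plot Profile" on a rectangular selection). For
#' RGB micrographs of a blue dye the default is the blue plane.
#'
#' @param image A [channel_image()].
#' @param channel Color plane: `"blue"` (default), `"green"`, `"red"`, or
#'   `"luma"`. Ignored for grayscale images.
#' @param roi Optional ROI overriding the image's own.
#' @return An [intensity_profile()] with raw (un-normalized) intensities;
#'   positions are pixel centres in um relative to the ROI's left edge.
#' @export
extract_profile <- function(image, channel = "blue", roi = NULL) {
  stopifnot(inherits(image, "channel_image"))
  if (is.null(roi)) roi <- image$roi
  validate_roi(roi, dim(image$pixels)[1], dim(image$pixels)[2])
  plane <- select_plane(image$pixels, channel)
  rows <- roi$rows[1]:roi$rows[2]
  cols <- roi$cols[1]:roi$cols[2]
  block <- plane[rows, cols, drop = FALSE]
  intensities <- colMeans(block)
  positions <- (seq_along(cols) - 0.5) * image$pixel_size
  intensity_profile(positions, unname(intensities))
}

#' Normalize a profile to the [0, 1] dye scale
#'
#' Maps the chip-background reference `lo_ref` to 0 and the undiluted-dye
#' reference `hi_ref` to 1, clamping values outside the references.
#'
#' @param profile An [intensity_profile()].
#' @param lo_ref Background intensity reference (gray value 0).
#' @param hi_ref Dye plateau intensity reference (gray value 1). Must
#'   exceed `lo_ref`.
#' @return A normalized [intensity_profile()].
#' @export
normalize_profile <- function(profile, lo_ref, hi_ref) {
  stopifnot(inherits(profile, "intensity_profile"))
  check_scalar(lo_ref, "lo_ref")
  check_scalar(hi_ref, "hi_ref")
  if (hi_ref <= lo_ref) stop("`hi_ref` must exceed `lo_ref`", call. = FALSE)
  scaled <- clamp((profile$intensities - lo_ref) / (hi_ref - lo_ref), 0, 1)
  intensity_profile(profile$positions, scaled)
}

#' Absolute mixing index (AMI)
#'
#' The population coefficient of variation of the cross-width intensity
#' profile: `AMI = sqrt(mean((I - <I>)^2)) / <I>`. Zero indicates complete
#' mixing (a flat profile); larger values indicate residual cross-channel
#' segregation. Invariant under intensity rescaling `I -> a I`, `a > 0`.
#'
#' @param profile An [intensity_profile()] or a plain numeric vector of
#'   intensities (n >= 2, positive mean).
#' @return AMI, dimensionless >= 0.
#' @examples
#' absolute_mixing_index(c(0, 0, 2, 2)) # 1: fully segregated two-level profile
#' @export
absolute_mixing_index <- function(profile) {
  x <- if (inherits(profile, "intensity_profile")) profile$intensities
       else profile
  check_numeric_vector(x, "intensities")
  if (length(x) < 2L) stop("profile needs at least 2 pixels", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("mean intensity is zero; AMI undefined", call. = FALSE)
  sqrt(mean((x - m)^2)) / m
}

#' Least-squares slope of intensity versus cross-width position
#'
#' A complementary mixing metric: complete mixing yields a slope of zero
#' for intensity vs distance across the channel. The signed ordinary
#' least-squares slope is returned; use `abs = TRUE` for the magnitude.
#'
#' @param profile An [intensity_profile()] (n >= 2, non-degenerate
#'   positions).
#' @param abs Return the absolute slope? Default `FALSE` (signed).
#' @return Slope in 1/um (intensity units per um).
#' @export
profile_slope <- function(profile, abs = FALSE) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (profile$n < 2L) stop("profile needs at least 2 points", call. = FALSE)
  if (diff(range(profile$positions)) == 0) {
    stop("degenerate positions (all equal)", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, profile$positions),
                       profile$intensities)
  s <- unname(fit$coefficients[2])
  if (abs) base::abs(s) else s
}

#' Estimate end-of-mixer dilution fractions from four channel images
#'
#' Interpolates mean ROI intensities of the four output channels between
#' the 100% channel (A, undiluted dye) and the 0% channel (D, buffer):
#' `fraction_k = 100 * (I_k - I_D) / (I_A - I_D)`. Invariant under affine
#' intensity transforms applied to all four images.
#'
#' @param end_images List of four [channel_image()]s ordered A, B, C, D
#'   (A = 100% inlet, D = 0% inlet).
#' @param channel Color plane used for the mean intensity (default blue).
#' @return Named numeric vector of fractions (% of inlet concentration),
#'   names `A`-`D`; A is 100 and D is 0 by construction.
#' @export
estimate_dilution <- function(end_images, channel = "blue") {
  if (!is.list(end_images) || length(end_images) != 4L) {
    stop("`end_images` must be a list of four channel_image objects",
         call. = FALSE)
  }
  means <- vapply(end_images, function(im) {
    stopifnot(inherits(im, "channel_image"))
    roi <- im$roi
    plane <- select_plane(im$pixels, channel)
    mean(plane[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2]])
  }, numeric(1))
  span <- means[1] - means[4]
  if (span == 0) {
    stop("no contrast between the 100% and 0% channels", call. = FALSE)
  }
  fractions <- 100 * (means - means[4]) / span
  stats::setNames(fractions, c("A", "B", "C", "D"))
}

#' Linear dependence of a mixing metric on volumetric flow rate
#'
#' Ordinary least-squares fit of a mixing metric (AMI or profile slope)
#' against volumetric flow rate, with the coefficient of determination.
#'
#' @param flow_rate Volumetric flow rates, uL/min (>= 3 distinct values).
#' @param metric Mixing metric at each flow rate (AMI or slope).
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
mixing_vs_flowrate <- function(flow_rate, metric) {
  check_numeric_vector(flow_rate, "flow_rate")
  check_numeric_vector(metric, "metric")
  if (length(flow_rate) != length(metric)) {
    stop("`flow_rate` and `metric` must have equal length", call. = FALSE)
  }
  if (length(flow_rate) < 3L) {
    stop("need at least 3 (flow rate, metric) pairs", call. = FALSE)
  }
  if (length(unique(flow_rate)) < 2L) {
    stop("flow rates are all equal; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(metric ~ flow_rate)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((metric - mean(metric))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}
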