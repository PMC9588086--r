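# Seeded generators for every input the analysis chain consumes. Each one
# is a pure function of its arguments + seed and returns its ground truth
# alongside the data, so every analysis stage has a closed-loop test.

#' Simulate a two-stream mixing-channel micrograph
#'
#' Emulates an RGB micrograph of a serpentine mixing channel carrying dye
#' on one side and buffer on the other. The cross-width concentration
#' follows the 1-D interdiffusion profile
#' `c(y) = (1 + erf((y - w/2) / (2 sqrt(D t_res)))) / 2` at residence time
#' `t_res = downstream_len / velocity`; `downstream_len = 0` gives the
#' unmixed step, and long residence times flatten the profile towards the
#' fully mixed 1/2. Concentration is encoded linearly into the blue plane
#' between `background_level` and `dye_level`; red and green stay at
#' background. Gaussian pixel noise is added and intensities clamped to
#' [0, 1].
#'
#' @param width_px,height_px Image size in pixels (width spans the
#'   channel).
#' @param channel_width Channel width, um.
#' @param diffusivity Dye diffusivity, m^2/s.
#' @param velocity Mean linear velocity, m/s, > 0.
#' @param downstream_len Distance travelled downstream, m, >= 0.
#' @param dye_level,background_level Blue-plane intensities of undiluted
#'   dye and chip background, in [0, 1].
#' @param noise_sd Gaussian pixel noise SD (intensity units), >= 0.
#' @param seed RNG seed for the noise.
#' @return A list with `image` (a [channel_image()], RGB), `truth` (the
#'   noise-free concentration profile as an [intensity_profile()] in
#'   [0, 1]), and `residence_time` (s).
#' @export
make_mixing_image <- function(width_px = 192L, height_px = 48L,
                              channel_width = 150,
                              diffusivity = 3.31e-10,
                              velocity = 1.11e-3,
                              downstream_len = 18.5e-3,
                              dye_level = 0.85, background_level = 0.08,
                              noise_sd = 0.01, seed = 1L) {
  check_scalar(width_px, "width_px", positive = TRUE)
  check_scalar(height_px, "height_px", positive = TRUE)
  check_scalar(channel_width, "channel_width", positive = TRUE)
  check_scalar(diffusivity, "diffusivity", positive = TRUE)
  check_scalar(velocity, "velocity", positive = TRUE)
  check_scalar(downstream_len, "downstream_len", non_negative = TRUE)
  check_scalar(noise_sd, "noise_sd", non_negative = TRUE)
  pixel_size <- channel_width / width_px
  y_um <- (seq_len(width_px) - 0.5) * pixel_size
  t_res <- downstream_len / velocity
  if (t_res > 0) {
    spread_um <- 2 * sqrt(diffusivity * t_res) * 1e6
    conc <- 0.5 * (1 + erf((y_um - channel_width / 2) / spread_um))
  } else {
    conc <- as.numeric(y_um > channel_width / 2) +
      0.5 * (y_um == channel_width / 2)
  }
  blue_row <- background_level + (dye_level - background_level) * conc
  img <- array(background_level, dim = c(height_px, width_px, 3L))
  img[, , 3] <- matrix(blue_row, nrow = height_px, ncol = width_px,
                       byrow = TRUE)
  if (noise_sd > 0) {
    img <- with_seed_if(seed, img + stats::rnorm(length(img), 0, noise_sd))
  }
  img <- clamp(img, 0, 1)
  list(image = channel_image(img, pixel_size = pixel_size),
       truth = intensity_profile(y_um, conc),
       residence_time = t_res)
}

#' Simulate a two-channel live/dead cell micrograph
#'
#' Places bright disks (cells) at seeded random positions in a two-plane
#' image: plane 1 holds live cells (membrane dye), plane 2 dead cells
#' (nuclear stain). By default placements are non-overlapping across both
#' planes, matching the countability assumption of a manual live/dead
#' count; packing is attempted with a bounded number of rejections.
#'
#' @param n_live,n_dead Cell counts, >= 0.
#' @param cell_radius_px Disk radius, pixels, >= 1.
#' @param width_px,height_px Field size, pixels.
#' @param live_level,dead_level Disk intensities per plane.
#' @param background Background intensity of both planes.
#' @param overlap Allow overlapping cells? Default `FALSE`.
#' @param noise_sd Gaussian pixel noise SD, >= 0.
#' @param seed RNG seed.
#' @param max_tries Placement attempts per cell before giving up.
#' @return A list with `image` (`height_px x width_px x 2` array),
#'   `n_live`, `n_dead`, and `centers` (data.frame of placed cells).
#' @export
make_cell_image <- function(n_live, n_dead, cell_radius_px = 4L,
                            width_px = 160L, height_px = 160L,
                            live_level = 0.9, dead_level = 0.9,
                            background = 0.05, overlap = FALSE,
                            noise_sd = 0, seed = 1L, max_tries = 2000L) {
  check_scalar(n_live, "n_live", non_negative = TRUE)
  check_scalar(n_dead, "n_dead", non_negative = TRUE)
  check_scalar(cell_radius_px, "cell_radius_px", positive = TRUE)
  if (cell_radius_px < 1) stop("`cell_radius_px` must be >= 1", call. = FALSE)
  check_scalar(noise_sd, "noise_sd", non_negative = TRUE)
  r <- cell_radius_px
  n_total <- n_live + n_dead
  centers <- with_seed_if(seed, {
    placed <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n_total)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- stats::runif(1, r + 1, width_px - r)
        cy <- stats::runif(1, r + 1, height_px - r)
        if (overlap || nrow(placed) == 0 ||
            all((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2 >
                (2 * r + 1)^2)) {
          placed <- rbind(placed, c(cx, cy))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(paste0("could not place %d non-overlapping cells of ",
                            "radius %d in a %d x %d field"),
                     n_total, as.integer(r), width_px, height_px),
             call. = FALSE)
      }
    }
    placed
  })
  img <- array(background, dim = c(height_px, width_px, 2L))
  if (n_total > 0) {
    xs <- matrix(rep(seq_len(width_px), each = height_px), nrow = height_px)
    ys <- matrix(rep(seq_len(height_px), times = width_px), nrow = height_px)
    for (i in seq_len(n_total)) {
      disk <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= r^2
      plane <- if (i <= n_live) 1L else 2L
      level <- if (plane == 1L) live_level else dead_level
      slab <- img[, , plane]
      slab[disk] <- level
      img[, , plane] <- slab
    }
  }
  if (noise_sd > 0) {
    img <- clamp(with_seed_if(seed + 1L,
                              img + stats::rnorm(length(img), 0, noise_sd)),
                 0, 1)
  }
  centers_df <- if (n_total > 0) {
    data.frame(x = centers[, 1], y = centers[, 2],
               state = rep(c("live", "dead"), c(n_live, n_dead)))
  } else {
    data.frame(x = numeric(0), y = numeric(0), state = character(0))
  }
  list(image = img, n_live = as.integer(n_live),
       n_dead = as.integer(n_dead), centers = centers_df)
}

#' Count live and dead cells in a two-channel image
#'
#' Thresholds each plane, labels connected components (via
#' \pkg{EBImage}'s `bwlabel`, 4-connectivity) and discards components
#' smaller than `min_area_px`. Plane 1 is counted as live, plane 2 as
#' dead.
#'
#' @param image `h x w x 2` numeric array (e.g. from
#'   [make_cell_image()]).
#' @param threshold Intensity threshold separating cells from background.
#' @param min_area_px Minimum component area in pixels.
#' @return A list with `n_live`, `n_dead`, and `blank` (logical vector per
#'   plane: no above-threshold pixels found).
#' @export
count_cells <- function(image, threshold = 0.5, min_area_px = 1L) {
  if (!is.numeric(image) || length(dim(image)) != 3L || dim(image)[3] != 2L) {
    stop("`image` must be an h x w x 2 numeric array", call. = FALSE)
  }
  check_scalar(threshold, "threshold")
  check_scalar(min_area_px, "min_area_px", positive = TRUE)
  count_plane <- function(plane) {
    bw <- plane > threshold
    if (!any(bw)) return(c(count = 0L, blank = 1L))
    labels <- EBImage::bwlabel(bw)
    areas <- tabulate(labels[labels > 0])
    c(count = sum(areas >= min_area_px), blank = 0L)
  }
  live <- count_plane(image[, , 1])
  dead <- count_plane(image[, , 2])
  blank <- c(live = unname(live["blank"]) == 1,
             dead = unname(dead["blank"]) == 1)
  if (any(blank)) {
    warning(sprintf("no above-threshold pixels in plane(s): %s",
                    paste(names(blank)[blank], collapse = ", ")),
            call. = FALSE)
  }
  list(n_live = unname(live["count"]), n_dead = unname(dead["count"]),
       blank = unname(blank))
}

#' Simulate an FCS autocorrelation curve
#'
#' Evaluates the triplet-model autocorrelation on a lag grid and applies
#' seeded multiplicative Gaussian noise,
#' `G_obs = G (1 + noise_frac * eps)`.
#'
#' @param params An [fcs_params()] ground truth.
#' @param lags Lag grid, s (strictly increasing, > 0). Default 50
#'   log-spaced lags over 1e-6..1e-2 s.
#' @param noise_frac Multiplicative noise fraction, >= 0.
#' @param seed RNG seed.
#' @param p_squared Axial-factor convention, see [fcs_autocorrelation()].
#' @return A list with `curve` (an [fcs_curve()]) and `params` (the
#'   generating truth).
#' @export
make_fcs_curve <- function(params,
                           lags = 10^seq(-6, -2, length.out = 50),
                           noise_frac = 0.02, seed = 1L,
                           p_squared = TRUE) {
  stopifnot(inherits(params, "fcs_params"))
  check_scalar(noise_frac, "noise_frac", non_negative = TRUE)
  g <- fcs_autocorrelation(lags, params, p_squared = p_squared)
  if (noise_frac > 0) {
    g <- with_seed_if(seed,
                      g * (1 + stats::rnorm(length(g), 0, noise_frac)))
  }
  list(curve = fcs_curve(lags, g), params = params)
}

#' Simulate a dose-response viability table
#'
#' Evaluates [hill_viability()] at the requested doses, adds seeded
#' Gaussian noise (in viability percentage points) and clamps to
#' [0, 100].
#'
#' @param top,bottom,ec50,hill Ground-truth Hill parameters.
#' @param doses Dose grid, >= 0.
#' @param noise_sd Gaussian noise SD in percentage points, >= 0.
#' @param seed RNG seed.
#' @return A list with `data` (data.frame `dose`, `viability`) and
#'   `truth` (named list of the generating parameters).
#' @export
make_dose_response <- function(top = 90, bottom = 10, ec50 = 0.61,
                               hill = 2, doses = c(0, 0.25, 0.5, 1, 2, 4),
                               noise_sd = 0, seed = 1L) {
  check_scalar(top, "top"); check_scalar(bottom, "bottom")
  check_scalar(ec50, "ec50", positive = TRUE)
  check_scalar(hill, "hill", positive = TRUE)
  check_numeric_vector(doses, "doses", non_negative = TRUE)
  check_scalar(noise_sd, "noise_sd", non_negative = TRUE)
  v <- hill_viability(doses, top, bottom, ec50, hill)
  if (noise_sd > 0) {
    v <- with_seed_if(seed, v + stats::rnorm(length(v), 0, noise_sd))
  }
  list(data = data.frame(dose = doses, viability = clamp(v, 0, 100)),
       truth = list(top = top, bottom = bottom, ec50 = ec50, hill = hill))
}
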