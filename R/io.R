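# Readers/writers for the formats the pipeline touches: PNG/TIFF images,
# CSV tables (comma-separated, header row, UTF-8, '.' decimal), YAML
# network/pipeline configs and JSON reports.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  stop(sprintf("unsupported image extension '.%s' (use .png or .tif/.tiff)",
               ext), call. = FALSE)
}

#' Write an image to PNG or TIFF
#'
#' Accepts a [channel_image()], matrix or array with values in [0, 1].
#' TIFF output can be written as 8-bit, 16-bit or 32-bit float samples.
#'
#' @param image Image data ([channel_image()], matrix or array in [0, 1]).
#' @param path Output path, extension `.png`, `.tif` or `.tiff`.
#' @param bits Bits per sample for TIFF (8, 16 or 32 = float); PNG is
#'   written 16-bit for `bits >= 16`, 8-bit otherwise.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  px <- if (inherits(image, "channel_image")) image$pixels else image
  if (!is.numeric(px) || any(!is.finite(px))) {
    stop("image data must be finite numeric", call. = FALSE)
  }
  if (min(px) < 0 || max(px) > 1) {
    stop("image intensities must be in [0, 1] for writing", call. = FALSE)
  }
  fmt <- img_format(path)
  if (fmt == "png") {
    png::writePNG(px, target = path, dpi = NULL)
  } else {
    if (bits == 32) {
      tiff::writeTIFF(px, path, bits.per.sample = 32L)
    } else {
      tiff::writeTIFF(px, path, bits.per.sample = as.integer(bits))
    }
  }
  invisible(path)
}

#' Read a PNG or TIFF image
#'
#' @param path Image path, extension `.png`, `.tif` or `.tiff`.
#' @param pixel_size Pixel size in um/pixel to attach.
#' @param as_channel_image Wrap the array in a [channel_image()]?
#'   Default `TRUE`.
#' @return A [channel_image()] (or the bare array), intensities in [0, 1].
#' @export
read_image <- function(path, pixel_size = 1, as_channel_image = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  fmt <- img_format(path)
  px <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  # drop an alpha plane if present
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]
  if (as_channel_image) channel_image(px, pixel_size = pixel_size) else px
}

# Shared CSV reader that names any missing required column.
read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Read/write an FCS correlation curve as CSV
#'
#' Columns `lag_s` (lag time, s) and `g` (correlation amplitude).
#'
#' @param path CSV path.
#' @return `read_fcs_csv()`: an [fcs_curve()]. `write_fcs_csv()`: `path`,
#'   invisibly.
#' @export
read_fcs_csv <- function(path) {
  df <- read_csv_checked(path, c("lag_s", "g"))
  fcs_curve(df$lag_s, df$g)
}

#' @rdname read_fcs_csv
#' @param curve An [fcs_curve()].
#' @export
write_fcs_csv <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_curve"))
  utils::write.csv(data.frame(lag_s = curve$lags, g = curve$g),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response table from CSV
#'
#' Columns `dose` and `viability` (percent); an optional `replicate`
#' column is carried through.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_dose_csv <- function(path) {
  read_csv_checked(path, c("dose", "viability"))
}

#' Read a molecule panel from CSV
#'
#' Columns `name`, `mw_g_per_mol`, `density_g_per_cm3`.
#'
#' @param path CSV path.
#' @return A list of [molecule()] objects.
#' @export
read_molecules_csv <- function(path) {
  df <- read_csv_checked(path, c("name", "mw_g_per_mol",
                                 "density_g_per_cm3"))
  lapply(seq_len(nrow(df)), function(i) {
    molecule(df$name[i], df$mw_g_per_mol[i], df$density_g_per_cm3[i])
  })
}

#' Read a dilution-network spec from YAML
#'
#' The YAML mirrors the structure accepted by [ladder_fractions()]:
#' `inlets` (name: concentration), `stages` (name: list of
#' `{weight, source}`), `outputs` (ordered list of node names).
#'
#' @param path YAML path.
#' @return A validated network list.
#' @export
read_network_yaml <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  net <- yaml::read_yaml(path)
  missing <- setdiff(c("inlets", "stages", "outputs"), names(net))
  if (length(missing)) {
    stop(sprintf("%s: missing network element(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  net$outputs <- as.character(unlist(net$outputs))
  net
}
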