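#' Snapshot mosaic camera model
#'
#' Describes the 4x4 spectral-filter-on-CMOS snapshot sensor: sixteen
#' 10 nm bands spanning 460-620 nm, the per-band flat-field references,
#' and the fixed bijection between spectral band and position inside each
#' 4x4 super-pixel.  The full sensor is `4*height x 4*width` photosites,
#' demosaiced into a `height x width x 16` hyperspectral cube
#' (1088 x 2048 -> 272 x 512 at the native resolution).
#'
#' @param height,width Hyperspectral cube dimensions in pixels (the raw
#'   frame is 4x larger in each dimension).
#' @param band_centers Strictly increasing band-center wavelengths (nm),
#'   within \[460, 620\].  Default: 465 + 10 b for b = 0..15, i.e. the
#'   centers of sixteen 10-nm bands tiling 460-620 nm.
#' @param dark_level Sensor dark level in digital numbers (DN).
#' @param white_reference Per-band white reference (DN at unit
#'   reflectance).  Default is a smooth quantum-efficiency-like profile
#'   peaking mid-spectrum.
#' @param read_noise_sd Additive read noise SD in DN.
#' @param saturation_dn Saturation ceiling in DN (16-bit sensor: 65535).
#' @param mosaic_offset 16 x 2 integer matrix; row b gives the 0-based
#'   (row, col) position of band b inside each 4x4 super-pixel.  Must be
#'   a bijection onto \{0..3\} x \{0..3\}.  Default: band b at
#'   (b div 4, b mod 4).
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(height = 8, width = 12)
#' cam$band_centers
#' @export
camera_model <- function(height = 272L, width = 512L,
                         band_centers = seq(465, 615, by = 10),
                         dark_level = 64,
                         white_reference = NULL,
                         read_noise_sd = 30,
                         saturation_dn = 65535,
                         mosaic_offset = NULL) {
  n_bands <- length(band_centers)
  if (n_bands != 16L) {
    stop_retispec("camera_model requires exactly 16 band centers",
                  "retispec_parameter_error")
  }
  if (any(diff(band_centers) <= 0) ||
      min(band_centers) < 460 || max(band_centers) > 620) {
    stop_retispec(
      "band_centers must be strictly increasing within [460, 620] nm",
      "retispec_parameter_error")
  }
  if (is.null(white_reference)) {
    # smooth sensitivity profile, peak near 540 nm, well below saturation
    white_reference <- round(45000 + 12000 * exp(-((band_centers - 540) / 80)^2))
  }
  if (length(white_reference) != n_bands || any(white_reference <= dark_level)) {
    stop_retispec("white_reference must exceed dark_level in every band",
                  "retispec_calibration_error")
  }
  if (is.null(mosaic_offset)) {
    b <- 0:15
    mosaic_offset <- cbind(row = b %/% 4L, col = b %% 4L)
  }
  mosaic_offset <- matrix(as.integer(mosaic_offset), ncol = 2,
                          dimnames = list(NULL, c("row", "col")))
  key <- mosaic_offset[, 1] * 4L + mosaic_offset[, 2]
  if (nrow(mosaic_offset) != 16L || !setequal(key, 0:15) ||
      anyDuplicated(key) > 0) {
    stop_retispec("mosaic_offset must be a bijection band <-> 4x4 cell",
                  "retispec_parameter_error")
  }
  structure(list(
    height = as.integer(height), width = as.integer(width),
    band_centers = as.numeric(band_centers),
    dark_level = as.numeric(dark_level),
    white_reference = as.numeric(white_reference),
    read_noise_sd = as.numeric(read_noise_sd),
    saturation_dn = as.numeric(saturation_dn),
    mosaic_offset = mosaic_offset
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("Snapshot mosaic camera model\n")
  cat(sprintf("  cube: %d x %d x 16  (raw frame %d x %d)\n",
              x$height, x$width, 4L * x$height, 4L * x$width))
  cat(sprintf("  bands: %g-%g nm (10 nm spacing)\n",
              min(x$band_centers), max(x$band_centers)))
  cat(sprintf("  dark %g DN, white %g-%g DN, saturation %g DN\n",
              x$dark_level, min(x$white_reference), max(x$white_reference),
              x$saturation_dn))
  invisible(x)
}
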