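#' Hyperspectral cube container
#'
#' Light S3 wrapper for an `H x W x 16` relative-reflectance array with
#' its band-center wavelengths.
#'
#' @param values `H x W x 16` array, finite and non-negative.
#' @param band_centers Band centers (nm).
#' @param subject_ref Optional subject identifier.
#' @return Object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(values, band_centers, subject_ref = NA_character_) {
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == length(band_centers))
  if (!all(is.finite(values)) || any(values < 0)) {
    stop_retispec("cube values must be finite and non-negative",
                  "retispec_parameter_error")
  }
  structure(list(values = values, band_centers = as.numeric(band_centers),
                 subject_ref = subject_ref),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Hyperspectral cube %s: %d x %d x %d, %g-%g nm\n",
              x$subject_ref, d[1], d[2], d[3],
              min(x$band_centers), max(x$band_centers)))
  invisible(x)
}

#' Convert a digital-number cube to relative reflectance
#'
#' Flat-field conversion with the camera's dark level and per-band white
#' reference:
#' `R = (DN - dark_level) / (white_reference[b] - dark_level)`,
#' clipped below at zero (read noise makes small negative numerators
#' inevitable).
#'
#' @param dn_cube `H x W x 16` array of raw digital numbers (e.g. from
#'   [demosaic()]).
#' @param camera A [camera_model()].
#' @param subject_ref Optional subject identifier carried on the cube.
#' @return A [hyperspectral_cube()].
#' @export
to_relative_reflectance <- function(dn_cube, camera, subject_ref = NA_character_) {
  stopifnot(inherits(camera, "camera_model"))
  denom <- camera$white_reference - camera$dark_level
  if (any(denom <= 0)) {
    stop_retispec("white reference must exceed dark level in every band",
                  "retispec_calibration_error")
  }
  refl <- sweep(sweep(dn_cube, 3, camera$dark_level, "-"), 3, denom, "/")
  refl[refl < 0] <- 0
  hyperspectral_cube(refl, camera$band_centers, subject_ref)
}

#' Saturation quality check on a raw frame
#'
#' Acquisition uses the maximum flash intensity that avoids saturation
#' outside the optic nerve head (ONH): the bright ONH is allowed to
#' saturate, the rest of the retina is not.  This check measures the
#' fraction of raw photosites at the saturation ceiling outside a disc
#' around the OD center and flags the frame unusable when it exceeds a
#' small tolerance.
#'
#' @param raw Raw mosaic frame (matrix, raw-sensor resolution).
#' @param od_center OD center as 0-based (x, y) in cube coordinates.
#' @param camera A [camera_model()].
#' @param onh_radius ONH exclusion radius in cube pixels (default 20,
#'   about the optic disc radius at the native scale).
#' @param threshold Maximum tolerated saturated fraction outside the ONH.
#' @return List of class `qc_report` with `saturated_fraction_outside_onh`
#'   and `usable`.
#' @export
check_saturation <- function(raw, od_center, camera, onh_radius = 20,
                             threshold = 0.001) {
  stopifnot(inherits(camera, "camera_model"))
  nr <- nrow(raw); nc <- ncol(raw)
  # raw-resolution coordinates: cube pixel k spans raw columns 4k..4k+3
  cx <- 4 * od_center[["x"]] + 1.5; cy <- 4 * od_center[["y"]] + 1.5
  r_raw <- 4 * onh_radius
  xg <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  yg <- matrix(rep(0:(nr - 1), nc), nr, nc)
  outside <- (xg - cx)^2 + (yg - cy)^2 > r_raw^2
  sat <- raw >= camera$saturation_dn
  frac <- if (any(outside)) sum(sat & outside) / sum(outside) else 0
  structure(list(saturated_fraction_outside_onh = frac,
                 usable = frac <= threshold,
                 threshold = threshold),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %.4f%% saturated outside ONH -> %s\n",
              100 * x$saturated_fraction_outside_onh,
              if (x$usable) "usable" else "NOT usable"))
  invisible(x)
}
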