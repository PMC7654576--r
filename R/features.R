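#' Standardize a 16-band ROI spectrum into a 14-feature vector
#'
#' Drops the first and last bands (the edge bands of a mosaic sensor are
#' the noisiest) and divides the remaining 14 values by their own mean, a
#' per-spectrum intensity normalization that removes overall brightness
#' differences between captures while preserving spectral shape.  The
#' result is scale-invariant (`standardize(c x) = standardize(x)`) and a
#' constant spectrum maps to a vector of ones.
#'
#' @param mean_reflectance Numeric vector of 16 strictly positive band
#'   means (or an `roi_spectrum` from [mean_roi_spectrum()]).
#' @param drop_bands Indices of the bands to drop (default first and last).
#' @return Numeric vector of length 14.
#' @export
standardize_spectrum <- function(mean_reflectance, drop_bands = c(1L, 16L)) {
  if (inherits(mean_reflectance, "roi_spectrum")) {
    mean_reflectance <- mean_reflectance$mean_reflectance
  }
  x <- as.numeric(mean_reflectance)
  if (length(x) != 16L) {
    stop_retispec("expected a 16-band spectrum", "retispec_standardization_error")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_retispec("spectrum values must be positive and finite",
                  "retispec_standardization_error")
  }
  s <- x[-drop_bands]
  s / mean(s)
}

#' Assemble a classifier feature vector
#'
#' Concatenates the 14 standardized spectral features (ascending
#' wavelength) with, for the `+RNFL` configurations, the five RNFL
#' thickness features in the order AVG, SUP, NAS, INF, TEM.
#'
#' @param spec14 Standardized spectrum of length 14.
#' @param rnfl Named numeric vector of 5 RNFL values (um) or `NULL` for
#'   the spectra-only configurations.
#' @param config_id One of `"S1"`, `"I2"`, `"S1+RNFL"`, `"I2+RNFL"` (any
#'   ROI id is accepted in place of S1/I2).
#' @return Numeric feature vector of length 14 or 19 with attribute
#'   `config_id`.
#' @export
assemble_features <- function(spec14, rnfl = NULL, config_id) {
  if (length(spec14) != 14L) {
    stop_retispec("spectral part must have length 14", "retispec_assembly_error")
  }
  with_rnfl <- grepl("\\+RNFL$", config_id)
  if (with_rnfl && is.null(rnfl)) {
    stop_retispec(sprintf("config %s requires RNFL features", config_id),
                  "retispec_assembly_error")
  }
  if (!with_rnfl && !is.null(rnfl)) {
    stop_retispec(sprintf("config %s does not take RNFL features", config_id),
                  "retispec_assembly_error")
  }
  out <- as.numeric(spec14)
  if (with_rnfl) {
    if (length(rnfl) != 5L) {
      stop_retispec("RNFL part must have length 5", "retispec_assembly_error")
    }
    ord <- c("AVG", "SUP", "NAS", "INF", "TEM")
    if (!is.null(names(rnfl)) && all(ord %in% names(rnfl))) {
      rnfl <- rnfl[ord]
    }
    out <- c(out, as.numeric(rnfl))
  }
  names(out) <- c(sprintf("b%02d", seq_len(14L)),
                  if (with_rnfl) c("RNFL_AVG", "RNFL_SUP", "RNFL_NAS",
                                   "RNFL_INF", "RNFL_TEM"))
  attr(out, "config_id") <- config_id
  out
}
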