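#' Segment retinal blood vessels in a reflectance cube
#'
#' Vessels are detected as dark tubular structures on the
#' hemoglobin-contrast image (the mean of the bands whose centers fall in
#' 540-580 nm, where blood absorbs strongly).  The pipeline is standard
#' fundus-image practice:
#' \enumerate{
#'   \item contrast normalization: divide the hemoglobin image by a
#'     heavily smoothed copy of itself, making the detector invariant to
#'     global intensity scaling and slow illumination gradients;
#'   \item a multiscale line/ridge filter: at each scale the
#'     scale-normalized most-negative Hessian eigenvalue of the inverted
#'     contrast image, maximized over scales;
#'   \item fixed-quantile thresholding of the ridge response (the top
#'     `keep_frac` fraction of pixels);
#'   \item removal of connected components smaller than `min_area` px.
#' }
#' The output is deterministic: no RNG is involved.
#'
#' @param cube A [hyperspectral_cube()] (or a plain `H x W x B` array plus
#'   `band_centers`).
#' @param band_centers Required if `cube` is a plain array.
#' @param hb_window Wavelength window (nm) defining the hemoglobin bands.
#' @param scales Ridge-filter smoothing scales (px), matched to vessel
#'   half-widths.
#' @param bg_sigma Smoothing scale (px) of the background estimate used
#'   for contrast normalization.
#' @param keep_frac Fraction of pixels kept by the quantile threshold.
#' @param min_area Minimum connected-component area (px).
#' @return `H x W` logical matrix; `TRUE` marks vessel pixels (to be
#'   excluded from ROI averaging).
#' @export
segment_vessels <- function(cube, band_centers = NULL,
                            hb_window = c(540, 580),
                            scales = c(1.5, 2.5, 3.5),
                            bg_sigma = 12, keep_frac = 0.11, min_area = 50L) {
  if (inherits(cube, "hyperspectral_cube")) {
    band_centers <- cube$band_centers
    values <- cube$values
  } else {
    if (is.null(band_centers)) {
      stop_retispec("band_centers required for a plain array",
                    "retispec_parameter_error")
    }
    values <- cube
  }
  hb_bands <- which(band_centers >= hb_window[1] & band_centers <= hb_window[2])
  if (!length(hb_bands)) {
    stop_retispec("no bands inside the hemoglobin window",
                  "retispec_parameter_error")
  }
  hb <- apply(values[, , hb_bands, drop = FALSE], c(1, 2), mean)

  # Gaussian kernels must fit the image: cap sigma so the 6-sigma support
  # stays inside the smaller image dimension (matters only for tiny inputs)
  sigma_cap <- (min(dim(hb)) - 2) / 6.5
  gblur_safe <- function(img, sigma) {
    s <- min(sigma, sigma_cap)
    if (s <= 0.3) return(img)
    as.matrix(EBImage::gblur(img, sigma = s, boundary = "replicate"))
  }

  bg <- gblur_safe(hb, bg_sigma)
  floor_bg <- 1e-12 * max(bg)
  if (max(bg) <= 0) return(matrix(FALSE, nrow(hb), ncol(hb)))
  ratio <- hb / pmax(bg, floor_bg)
  inv <- pmax(1 - ratio, 0)  # vessels bright

  kxx <- matrix(c(1, -2, 1), nrow = 1)
  kxy <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1) / 4, 3, 3)
  resp <- matrix(0, nrow(hb), ncol(hb))
  for (s in scales) {
    sm <- gblur_safe(inv, s)
    ixx <- as.matrix(EBImage::filter2(sm, kxx, boundary = "replicate"))
    iyy <- as.matrix(EBImage::filter2(sm, t(kxx), boundary = "replicate"))
    ixy <- as.matrix(EBImage::filter2(sm, kxy, boundary = "replicate"))
    lam_min <- 0.5 * ((ixx + iyy) - sqrt((ixx - iyy)^2 + 4 * ixy^2))
    resp <- pmax(resp, s^2 * pmax(-lam_min, 0))
  }
  if (max(resp) <= 0) return(matrix(FALSE, nrow(hb), ncol(hb)))
  thr <- stats::quantile(resp, 1 - keep_frac, names = FALSE)
  mask <- resp > thr & resp > 0
  if (!any(mask)) return(mask)

  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labels <- as.matrix(EBImage::imageData(labels))
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_area)
  mask <- matrix(labels %in% keep, nrow(mask), ncol(mask))
  mask
}
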