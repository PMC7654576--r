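#' Retinal landmarks
#'
#' Manually marked optic-disc center and fovea, in 0-based (x, y) pixel
#' coordinates (origin top-left, x = column, y = row), plus eye laterality.
#'
#' @param od_center,fovea Numeric (x, y) vectors.
#' @param eye `"right"` or `"left"`.
#' @return Object of class `landmarks`.
#' @export
landmarks <- function(od_center, fovea, eye = c("right", "left")) {
  eye <- match.arg(eye)
  od_center <- c(x = as.numeric(od_center[[1]]), y = as.numeric(od_center[[2]]))
  fovea <- c(x = as.numeric(fovea[[1]]), y = as.numeric(fovea[[2]]))
  if (all(od_center == fovea)) {
    stop_retispec("optic disc center and fovea must be distinct",
                  "retispec_landmark_error")
  }
  structure(list(od_center = od_center, fovea = fovea, eye = eye),
            class = "landmarks")
}

#' Place the four anatomical ROIs relative to the OD-fovea axis
#'
#' Works in a rotated frame in which the +u axis runs from the optic-disc
#' center towards the fovea and +v points to the anatomically superior
#' side.  Left eyes are mirrored horizontally first, so
#' superior/inferior semantics match right eyes.  All four rectangles are
#' horizontally centered at the OD-fovea midpoint (u = D/2), have height
#' 40 px and width `round(0.35 D)` where D is the OD-fovea distance; the
#' near edges of S1/I1 sit `near_offset * D` from the axis and those of
#' S2/I2 at `far_offset * D` (superior / inferior respectively).  The
#' rectangles are disjoint whenever the gap
#' `(far_offset - near_offset) * D` is at least the ROI height; the
#' offsets are validated against that and against the image bounds.  The
#' defaults (0.15 and 0.55) are the largest symmetric layout for which
#' all four ROIs fit a 272 x 512 capture across the OD-fovea distances
#' that produce the canonical 32-52 px width range.
#'
#' @param lm A [landmarks()] object.
#' @param image_shape `c(H, W)` of the hyperspectral cube.
#' @param height ROI height in px (default 40).
#' @param width_frac ROI width as a fraction of D (default 0.35).
#' @param near_offset,far_offset Near-edge offsets of S1/I1 and S2/I2 from
#'   the axis, as fractions of D (defaults 0.15 and 0.55).
#' @return Object of class `roi_set`: a list of four `roi_rect` entries
#'   (ids S1, S2, I1, I2 with integer half-open `[u0, u1) x [v0, v1)`
#'   bounds in the rotated frame) plus the rigid transform (mirrored
#'   origin, axis unit vectors, D).
#' @export
place_rois <- function(lm, image_shape, height = 40L, width_frac = 0.35,
                       near_offset = 0.15, far_offset = 0.55) {
  stopifnot(inherits(lm, "landmarks"))
  H <- image_shape[1]; W <- image_shape[2]
  mirror <- identical(lm$eye, "left")
  mx <- function(p) if (mirror) c(x = (W - 1) - p[["x"]], y = p[["y"]]) else p
  od <- mx(lm$od_center); fv <- mx(lm$fovea)
  d_vec <- c(fv[["x"]] - od[["x"]], fv[["y"]] - od[["y"]])
  D <- sqrt(sum(d_vec^2))
  if (D == 0) {
    stop_retispec("OD-fovea distance is zero", "retispec_landmark_error")
  }
  e1 <- d_vec / D                      # +u: OD -> fovea
  n <- c(e1[2], -e1[1])                # +v: superior (y axis points down)
  w <- as.integer(round(width_frac * D))
  h <- as.integer(height)
  if (near_offset * D + h > far_offset * D) {
    stop_retispec("near and far ROIs overlap at this OD-fovea distance",
                  "retispec_geometry_error")
  }
  u0 <- floor(D / 2 - w / 2)
  vn <- floor(near_offset * D); vf <- floor(far_offset * D)
  rects <- list(
    S1 = list(id = "S1", u0 = u0, u1 = u0 + w, v0 = vn,       v1 = vn + h),
    S2 = list(id = "S2", u0 = u0, u1 = u0 + w, v0 = vf,       v1 = vf + h),
    I1 = list(id = "I1", u0 = u0, u1 = u0 + w, v0 = -(vn + h), v1 = -vn),
    I2 = list(id = "I2", u0 = u0, u1 = u0 + w, v0 = -(vf + h), v1 = -vf)
  )
  transform <- list(origin = od, e1 = e1, n = n, D = D,
                    mirror = mirror, width = W, height_px = H)
  # every ROI must lie inside the image
  for (r in rects) {
    corners_u <- c(r$u0, r$u1, r$u0, r$u1)
    corners_v <- c(r$v0, r$v0, r$v1, r$v1)
    px <- od[["x"]] + corners_u * e1[1] + corners_v * n[1]
    py <- od[["y"]] + corners_u * e1[2] + corners_v * n[2]
    if (any(px < 0 | px > W - 1 | py < 0 | py > H - 1)) {
      stop_retispec(sprintf("ROI %s extends outside the image", r$id),
                    "retispec_geometry_error")
    }
  }
  structure(list(rois = rects, transform = transform,
                 width = w, height = h),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set: width %d px, height %d px, D = %.1f px (%s)\n",
              x$width, x$height, x$transform$D,
              if (x$transform$mirror) "left eye, mirrored" else "right eye"))
  for (r in x$rois) {
    cat(sprintf("  %s: u [%d, %d), v [%d, %d)\n", r$id, r$u0, r$u1, r$v0, r$v1))
  }
  invisible(x)
}

# Half-open membership of every cube pixel in one ROI rectangle:
# pixel (x, y) belongs to the ROI iff floor(u), floor(v) of its
# transformed coordinates fall inside the integer bounds.
roi_pixel_mask <- function(roi, transform, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  xs <- 0:(W - 1)
  if (transform$mirror) xs <- (W - 1) - xs
  relx <- matrix(rep(xs, each = H), H, W) - transform$origin[["x"]]
  rely <- matrix(rep(0:(H - 1), W), H, W) - transform$origin[["y"]]
  u <- floor(relx * transform$e1[1] + rely * transform$e1[2])
  v <- floor(relx * transform$n[1] + rely * transform$n[2])
  u >= roi$u0 & u < roi$u1 & v >= roi$v0 & v < roi$v1
}

#' Mean ROI spectrum with vessel exclusion
#'
#' Averages the relative-reflectance spectrum over all cube pixels whose
#' transformed coordinates fall inside the ROI rectangle (half-open
#' bounds) and that are not vessel-masked.
#'
#' @param cube A [hyperspectral_cube()].
#' @param roi One element of `roi_set$rois` (or an id present in
#'   `roi_set`).
#' @param roi_set The [place_rois()] result supplying the transform.
#' @param vessels Optional `H x W` logical vessel mask (`TRUE` excluded).
#' @return List of class `roi_spectrum`: `roi_id`, `mean_reflectance`
#'   (length 16), `n_pixels_used`.
#' @export
mean_roi_spectrum <- function(cube, roi, roi_set, vessels = NULL) {
  stopifnot(inherits(cube, "hyperspectral_cube"), inherits(roi_set, "roi_set"))
  if (is.character(roi)) roi <- roi_set$rois[[roi]]
  d <- dim(cube$values)
  mask <- roi_pixel_mask(roi, roi_set$transform, d[1:2])
  if (!is.null(vessels)) mask <- mask & !vessels
  idx <- which(mask)
  if (!length(idx)) {
    stop_retispec(sprintf("ROI %s has no usable (non-vessel) pixels", roi$id),
                  "retispec_empty_roi_error")
  }
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  structure(list(roi_id = roi$id,
                 mean_reflectance = colMeans(flat[idx, , drop = FALSE]),
                 n_pixels_used = length(idx)),
            class = "roi_spectrum")
}
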