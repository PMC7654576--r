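#' Generate a synthetic retinal phantom for one subject
#'
#' Builds a ground-truthed retinal reflectance phantom at cube resolution:
#' a smooth background spectrum with low-frequency spatial variation, a
#' bright optic disc and a darker macula, a rasterized vessel tree with
#' hemoglobin-like absorption (broadband darkening plus a dip centered at
#' 560 nm, i.e. inside the 540-580 nm bands), and -- for AD subjects -- a
#' Rayleigh-scattering attenuation: every band is multiplied by
#' `1 - a * amyloid_load * (460 / lambda)^4`, so the reflectance loss is
#' maximal below 550 nm and decays as wavelength^-4.  Per-pixel Gaussian
#' noise of SD `pixel_noise_sd` (relative-reflectance units) is added last
#' and the result clipped at zero.
#'
#' Landmarks follow a macula-centered capture: the fovea sits near the
#' image center and the optic disc one disc-fovea distance away along the
#' horizontal; left eyes are mirrored (fovea left of the OD) so the
#' laterality handling of the ROI geometry is exercised.
#'
#' @param subject One row of the data frame returned by [generate_cohort()].
#' @param camera A [camera_model()]; sets cube dimensions and band centers.
#' @param seed Integer seed; the phantom is deterministic given
#'   (subject, camera, seed).
#' @param scatter_amplitude Effect strength `a` in \[0, 1\] (see
#'   [cohort_spec()]).
#' @param pixel_noise_sd Per-pixel reflectance noise SD; 0 disables noise.
#' @param vessel_dip_depth Depth of the hemoglobin absorption dip at
#'   560 nm (fraction of local reflectance).
#' @param vessel_broadband Broadband vessel darkening (fraction).
#' @param vessel_coverage Target vessel area fraction; the rasterizer
#'   keeps the realized fraction within \[0.05, 0.15\].
#' @return Object of class `retinal_phantom`: fields `height`, `width`,
#'   `od_center`, `fovea` (0-based (x, y) pixel coordinates), `eye`,
#'   `vessel_truth` (H x W logical), `base_reflectance` (H x W x 16),
#'   `band_centers`, `subject_ref`.
#' @export
generate_phantom <- function(subject, camera, seed = 1L,
                             scatter_amplitude = 0.1,
                             pixel_noise_sd = 0.02,
                             vessel_dip_depth = 0.45,
                             vessel_broadband = 0.25,
                             vessel_coverage = 0.09) {
  stopifnot(inherits(camera, "camera_model"))
  H <- camera$height; W <- camera$width
  lam <- camera$band_centers
  with_seed(seed, {
    # --- landmarks (0-based pixel coordinates, x = column, y = row) ---
    fovea <- c(x = W / 2 + stats::rnorm(1, 0, 0.01 * W),
               y = H / 2 + stats::rnorm(1, 0, 0.01 * H))
    D <- min(max(stats::rnorm(1, 0.24 * W, 0.02 * W), 0.20 * W), 0.285 * W)
    dy_od <- stats::rnorm(1, 0, 0.02 * H)
    od <- if (identical(subject$eye, "left")) {
      c(x = fovea[["x"]] + D, y = fovea[["y"]] + dy_od)
    } else {
      c(x = fovea[["x"]] - D, y = fovea[["y"]] + dy_od)
    }
    od <- c(x = round(od[[1]]), y = round(od[[2]]))
    fovea <- c(x = round(fovea[[1]]), y = round(fovea[[2]]))

    # --- smooth spatial background ---
    xg <- matrix(rep(0:(W - 1), each = H), H, W)  # x index per pixel
    yg <- matrix(rep(0:(H - 1), W), H, W)
    gain <- 1
    for (k in 1:2) {
      fx <- stats::runif(1, 0.5, 1.5); fy <- stats::runif(1, 0.5, 1.5)
      px <- stats::runif(1, 0, 2 * pi); py <- stats::runif(1, 0, 2 * pi)
      gain <- gain + 0.05 * sin(2 * pi * fx * xg / W + px) *
                            sin(2 * pi * fy * yg / H + py)
    }
    d_f2 <- (xg - fovea[["x"]])^2 + (yg - fovea[["y"]])^2
    d_od2 <- (xg - od[["x"]])^2 + (yg - od[["y"]])^2
    gain <- gain * (1 - 0.12 * exp(-d_f2 / (2 * (0.06 * W)^2))) *
                   (1 + 0.60 * exp(-d_od2 / (2 * (0.035 * W)^2)))

    # --- vessel tree ---
    vessels <- rasterize_vessel_tree(H, W, od, vessel_coverage)

    # --- spectrum ---
    # gentle red rise; slope chosen so the lambda^-4 attenuation dominates
    # and the AD-CTRL difference decays monotonically with wavelength
    base_spec <- 0.25 + 0.33 * stats::plogis((lam - 560) / 45)
    ad_factor <- 1 - scatter_amplitude * subject$amyloid_load * (460 / lam)^4
    hb_factor <- 1 - vessel_broadband -
      vessel_dip_depth * exp(-((lam - 560)^2) / (2 * 18^2))

    cube <- array(0, dim = c(H, W, length(lam)))
    vidx <- which(vessels)
    for (b in seq_along(lam)) {
      plane <- gain * (base_spec[b] * ad_factor[b])
      plane[vidx] <- plane[vidx] * hb_factor[b]
      cube[, , b] <- plane
    }
    if (pixel_noise_sd > 0) {
      cube <- cube + stats::rnorm(length(cube), 0, pixel_noise_sd)
    }
    cube[cube < 0] <- 0

    phantom <- structure(list(
      height = H, width = W,
      od_center = od, fovea = fovea,
      eye = subject$eye %||% "right",
      vessel_truth = vessels,
      base_reflectance = cube,
      band_centers = lam,
      subject_ref = subject$subject_id %||% "unknown"
    ), class = "retinal_phantom")
    validate_phantom(phantom)
    phantom
  })
}

validate_phantom <- function(ph) {
  if (all(ph$od_center == ph$fovea)) {
    stop_retispec("optic disc and fovea coincide", "retispec_landmark_error")
  }
  cov <- mean(ph$vessel_truth)
  if (cov < 0.05 || cov > 0.15) {
    stop_retispec(sprintf("vessel coverage %.3f outside [0.05, 0.15]", cov),
                  "retispec_parameter_error")
  }
  if (!all(is.finite(ph$base_reflectance)) || any(ph$base_reflectance < 0)) {
    stop_retispec("base reflectance must be finite and non-negative",
                  "retispec_parameter_error")
  }
  invisible(ph)
}

# Rasterize a vessel tree as smooth random walks radiating from the optic
# disc, stamped with widths of 2-5 px.  Vessels are added until the area
# fraction reaches [0.05, 0.15], never knowingly exceeding the upper bound.
rasterize_vessel_tree <- function(H, W, od, target = 0.09) {
  mask <- matrix(FALSE, H, W)
  area <- H * W
  mean_len <- 0.9 * max(H, W)
  n_target <- max(2L, round(target * area / (mean_len * 3)))
  # thick trunks only where the image can afford them
  wmax <- if (H * W < 4096) 3L else 5L
  one_vessel <- function() {
    m <- matrix(FALSE, H, W)
    ang <- stats::runif(1, 0, 2 * pi)
    wdt <- sample(2:wmax, 1, prob = c(0.3, 0.4, 0.2, 0.1)[seq_len(wmax - 1)])
    x <- od[["x"]]; y <- od[["y"]]
    pts_x <- numeric(0); pts_y <- numeric(0)
    for (s in seq_len(round(mean_len))) {
      ang <- ang + stats::rnorm(1, 0, 0.06)
      x <- x + cos(ang); y <- y + sin(ang)
      if (x < 0 || x > W - 1 || y < 0 || y > H - 1) break
      pts_x <- c(pts_x, x); pts_y <- c(pts_y, y)
    }
    if (!length(pts_x)) return(m)
    r <- max(1L, floor(wdt / 2))
    off <- expand.grid(dx = -r:r, dy = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= r^2 + 0.5, ]
    for (k in seq_len(nrow(off))) {
      xs <- round(pts_x + off$dx[k]); ys <- round(pts_y + off$dy[k])
      keep <- xs >= 0 & xs <= W - 1 & ys >= 0 & ys <= H - 1
      m[cbind(ys[keep] + 1L, xs[keep] + 1L)] <- TRUE
    }
    m
  }
  n_drawn <- 0L
  while (mean(mask) < target || n_drawn < n_target) {
    cand <- one_vessel()
    new_cov <- mean(mask | cand)
    if (new_cov > 0.15) {
      if (mean(mask) >= 0.05) break
      # tiny images: thin the candidate down to the coverage ceiling
      idx_new <- which(cand & !mask)
      excess <- ceiling((new_cov - 0.15) * area)
      cand[sample(idx_new, min(excess, length(idx_new)))] <- FALSE
    }
    mask <- mask | cand
    n_drawn <- n_drawn + 1L
    if (n_drawn > 200L) break  # safety; never hit at sane sizes
  }
  mask
}

#' @export
print.retinal_phantom <- function(x, ...) {
  cat(sprintf("Retinal phantom %s (%s eye): %d x %d x %d\n", x$subject_ref,
              x$eye, x$height, x$width, length(x$band_centers)))
  cat(sprintf("  OD (%g, %g), fovea (%g, %g), vessel coverage %.1f%%\n",
              x$od_center[["x"]], x$od_center[["y"]],
              x$fovea[["x"]], x$fovea[["y"]], 100 * mean(x$vessel_truth)))
  invisible(x)
}
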