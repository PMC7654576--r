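# ROI geometry: widths, disjointness, laterality, equivariance; ROI
# averaging; spectral standardization; feature assembly.

big_lm <- function(D = 120, eye = "right", cx = 300, cy = 300) {
  if (eye == "right") landmarks(c(cx - D / 2, cy), c(cx + D / 2, cy), eye)
  else landmarks(c(cx + D / 2, cy), c(cx - D / 2, cy), eye)
}

test_that("ROI width follows round(0.35 D) across the canonical distance range", {
  shape <- c(700, 700)
  expect_equal(place_rois(big_lm(120), shape)$width, 42)
  expect_equal(place_rois(big_lm(100), shape)$width, 35)
  for (D in c(91.4, 100, 120, 148.6)) {
    rs <- place_rois(big_lm(D), shape, near_offset = 0.35, far_offset = 0.85)
    expect_equal(rs$width, round(0.35 * D))
    expect_gte(rs$width, 32)
    expect_lte(rs$width, 52)
  }
})

test_that("the four ROIs are pairwise disjoint and inside the image", {
  rs <- place_rois(big_lm(100), c(700, 700),
                   near_offset = 0.35, far_offset = 0.85)
  masks <- lapply(rs$rois, retispec:::roi_pixel_mask,
                  transform = rs$transform, image_shape = c(700, 700))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(any(masks[[i]] & masks[[j]]))
  }
  areas <- vapply(masks, sum, numeric(1))
  expect_true(all(areas > 0))
  # near/far gap below the ROI height is refused
  expect_error(place_rois(big_lm(60), c(700, 700)),
               class = "retispec_geometry_error")
  # ROI pushed outside a small image is refused
  expect_error(place_rois(big_lm(120, cx = 80, cy = 80), c(160, 160)),
               class = "retispec_geometry_error")
  expect_error(landmarks(c(5, 5), c(5, 5)),
               class = "retispec_landmark_error")
})

test_that("default layout fits the native frame for generator-range distances", {
  cam <- camera_model()
  for (seed in 1:6) {
    # native-scale landmarks drawn by the generator itself
    ph2 <- generate_phantom(manual_subject(id = "n", eye = if (seed %% 2) "right" else "left"),
                            cam, seed = seed)
    rs <- place_rois(landmarks(ph2$od_center, ph2$fovea, ph2$eye),
                     c(cam$height, cam$width))
    expect_s3_class(rs, "roi_set")
    expect_gte(rs$width, 32); expect_lte(rs$width, 52)
  }
})

test_that("ROI averaging matches hand-computed means and honors masks", {
  cube_vals <- array(0.4, c(60, 100, 16))
  cube <- hyperspectral_cube(cube_vals, seq(465, 615, 10))
  lm <- landmarks(c(30, 30), c(70, 30), "right")
  rs <- place_rois(lm, c(60, 100), height = 6L)
  sp <- mean_roi_spectrum(cube, "S1", rs)
  expect_equal(unname(sp$mean_reflectance), rep(0.4, 16))
  expect_gt(sp$n_pixels_used, 0)

  # two-pixel ROI: mean of the two spectra
  m <- retispec:::roi_pixel_mask(rs$rois$S1, rs$transform, c(60, 100))
  idx <- which(m)[1:2]
  vessels <- matrix(TRUE, 60, 100); vessels[idx] <- FALSE
  v2 <- cube_vals
  for (b in 1:16) {
    plane <- v2[, , b]
    plane[idx[1]] <- b; plane[idx[2]] <- 3 * b
    v2[, , b] <- plane
  }
  cube2 <- hyperspectral_cube(v2, seq(465, 615, 10))
  sp2 <- mean_roi_spectrum(cube2, "S1", rs, vessels)
  expect_equal(sp2$n_pixels_used, 2)
  expect_equal(unname(sp2$mean_reflectance), (1:16 + 3 * (1:16)) / 2)

  # fully masked ROI errors
  expect_error(mean_roi_spectrum(cube, "S1", rs, matrix(TRUE, 60, 100)),
               class = "retispec_empty_roi_error")
})

test_that("mirroring a right-eye capture and relabeling it left preserves ROI spectra", {
  cam <- small_camera(48, 80)
  ph <- generate_phantom(manual_subject("AD", load = 1, eye = "right"),
                         cam, seed = 31)
  cube <- hyperspectral_cube(ph$base_reflectance, cam$band_centers)
  rs <- place_rois(landmarks(ph$od_center, ph$fovea, "right"), c(48, 80),
                   height = 6L)
  mirrored_vals <- ph$base_reflectance[, 80:1, , drop = FALSE]
  cube_m <- hyperspectral_cube(mirrored_vals, cam$band_centers)
  flip <- function(p) c(x = 79 - p[["x"]], y = p[["y"]])
  rs_m <- place_rois(landmarks(flip(ph$od_center), flip(ph$fovea), "left"),
                     c(48, 80), height = 6L)
  for (id in c("S1", "S2", "I1", "I2")) {
    expect_equal(mean_roi_spectrum(cube_m, id, rs_m)$mean_reflectance,
                 mean_roi_spectrum(cube, id, rs)$mean_reflectance)
  }
})

test_that("ROI pixel sets are equivariant under exact 90-degree rotation", {
  H <- 90; W <- 120
  lm <- landmarks(c(40, 45), c(80, 45), "right")
  rs <- place_rois(lm, c(H, W), height = 8L)
  masks <- lapply(rs$rois, retispec:::roi_pixel_mask,
                  transform = rs$transform, image_shape = c(H, W))
  # rotate image 90 deg clockwise: (x, y) -> (H - 1 - y, x); new shape W x H
  rot <- function(p) c(x = (H - 1) - p[["y"]], y = p[["x"]])
  rs_r <- place_rois(landmarks(rot(lm$od_center), rot(lm$fovea), "right"),
                     c(W, H), height = 8L)
  masks_r <- lapply(rs_r$rois, retispec:::roi_pixel_mask,
                    transform = rs_r$transform, image_shape = c(W, H))
  for (id in c("S1", "S2", "I1", "I2")) {
    m <- masks[[id]]
    # apply the same rotation to the pixel set
    rot_m <- matrix(FALSE, W, H)
    ij <- which(m, arr.ind = TRUE)  # (row = y+1, col = x+1)
    x <- ij[, 2] - 1; y <- ij[, 1] - 1
    xr <- (H - 1) - y; yr <- x
    rot_m[cbind(yr + 1, xr + 1)] <- TRUE
    expect_equal(masks_r[[id]], rot_m)
  }
})

test_that("spectral standardization drops edge bands and normalizes scale", {
  x <- seq(0.2, 0.8, length.out = 16)
  s <- standardize_spectrum(x)
  expect_length(s, 14)
  expect_equal(mean(s), 1)
  expect_equal(standardize_spectrum(2 * x), s)           # scale invariance
  expect_equal(standardize_spectrum(c(rep(0.5, 16))), rep(1, 14))
  # idempotence on its own scale: re-normalizing changes nothing
  expect_equal(s / mean(s), s)
  expect_error(standardize_spectrum(c(-1, x[-1])),
               class = "retispec_standardization_error")
  expect_error(standardize_spectrum(x[1:10]),
               class = "retispec_standardization_error")
})

test_that("feature assembly yields 14 or 19 features with contract checks", {
  s14 <- standardize_spectrum(seq(0.2, 0.8, length.out = 16))
  rnfl <- c(AVG = 90, SUP = 105, NAS = 70, INF = 110, TEM = 65)
  f1 <- assemble_features(s14, NULL, "S1")
  expect_length(f1, 14)
  f2 <- assemble_features(s14, rnfl, "I2+RNFL")
  expect_length(f2, 19)
  expect_equal(unname(f2[15:19]), unname(rnfl[c("AVG", "SUP", "NAS", "INF", "TEM")]))
  expect_error(assemble_features(s14, NULL, "I2+RNFL"),
               class = "retispec_assembly_error")
  expect_error(assemble_features(s14, rnfl, "S1"),
               class = "retispec_assembly_error")
  expect_error(assemble_features(s14, rnfl[1:3], "S1+RNFL"),
               class = "retispec_assembly_error")
})
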