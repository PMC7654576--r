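#' Render a raw mosaic frame from a phantom
#'
#' Simulates the snapshot acquisition: each hyperspectral pixel (y, x)
#' occupies a 4x4 super-pixel of the raw sensor, and band b is sampled at
#' photosite `(4y + r, 4x + c)` with `(r, c) = mosaic_offset(b)`.  The
#' digital number is
#' `dark_level + reflectance * (white_reference[b] - dark_level)` plus
#' Gaussian read noise, rounded and clipped to `[0, saturation_dn]`.
#'
#' @param phantom A [generate_phantom()] result (dimensions must match the
#'   camera cube dimensions).
#' @param camera A [camera_model()].
#' @param seed Seed for the read noise; ignored when `read_noise_sd = 0`.
#' @return Integer matrix of dimension `4H x 4W` (class `raw_mosaic_frame`).
#' @export
render_raw_mosaic <- function(phantom, camera, seed = 1L) {
  stopifnot(inherits(camera, "camera_model"))
  H <- dim(phantom$base_reflectance)[1]
  W <- dim(phantom$base_reflectance)[2]
  if (H != camera$height || W != camera$width) {
    stop_retispec("phantom dimensions do not match camera cube dimensions",
                  "retispec_shape_error")
  }
  raw <- matrix(0, 4L * H, 4L * W)
  for (b in 1:16) {
    r <- camera$mosaic_offset[b, 1]; cc <- camera$mosaic_offset[b, 2]
    dn <- camera$dark_level + phantom$base_reflectance[, , b] *
      (camera$white_reference[b] - camera$dark_level)
    raw[seq(1L + r, by = 4L, length.out = H),
        seq(1L + cc, by = 4L, length.out = W)] <- dn
  }
  if (camera$read_noise_sd > 0) {
    raw <- raw + with_seed(seed,
      matrix(stats::rnorm(length(raw), 0, camera$read_noise_sd), nrow(raw)))
  }
  raw <- round(raw)
  raw[raw < 0] <- 0
  raw[raw > camera$saturation_dn] <- camera$saturation_dn
  structure(raw, class = c("raw_mosaic_frame", class(raw)))
}

#' Demosaic a raw frame into a digital-number cube
#'
#' Reorganizes the raw mosaic frame into an `H x W x 16` cube by pure
#' subsampling (no interpolation): `cube[y, x, b] = raw[4y + r, 4x + c]`
#' with `(r, c)` the mosaic offset of band b.  A 1088 x 2048 raw frame
#' yields a 272 x 512 x 16 cube.
#'
#' @param raw Numeric matrix with both dimensions divisible by 4.
#' @param camera A [camera_model()] supplying the mosaic offsets.
#' @return `H x W x 16` numeric array of raw digital numbers.
#' @seealso [mosaic_raw()] for the exact inverse.
#' @export
demosaic <- function(raw, camera) {
  stopifnot(inherits(camera, "camera_model"))
  if (nrow(raw) %% 4L != 0L || ncol(raw) %% 4L != 0L) {
    stop_retispec("raw frame dimensions must be multiples of 4",
                  "retispec_shape_error")
  }
  H <- nrow(raw) %/% 4L; W <- ncol(raw) %/% 4L
  cube <- array(0, dim = c(H, W, 16L))
  for (b in 1:16) {
    r <- camera$mosaic_offset[b, 1]; cc <- camera$mosaic_offset[b, 2]
    cube[, , b] <- raw[seq(1L + r, by = 4L, length.out = H),
                       seq(1L + cc, by = 4L, length.out = W)]
  }
  cube
}

#' Re-mosaic a digital-number cube into a raw frame
#'
#' Exact inverse of [demosaic()]: writes band b of each hyperspectral
#' pixel back to its photosite inside the 4x4 super-pixel.
#'
#' @param cube `H x W x 16` numeric array.
#' @param camera A [camera_model()].
#' @return `4H x 4W` numeric matrix.
#' @export
mosaic_raw <- function(cube, camera) {
  stopifnot(inherits(camera, "camera_model"), length(dim(cube)) == 3L,
            dim(cube)[3] == 16L)
  H <- dim(cube)[1]; W <- dim(cube)[2]
  raw <- matrix(0, 4L * H, 4L * W)
  for (b in 1:16) {
    r <- camera$mosaic_offset[b, 1]; cc <- camera$mosaic_offset[b, 2]
    raw[seq(1L + r, by = 4L, length.out = H),
        seq(1L + cc, by = 4L, length.out = W)] <- cube[, , b]
  }
  raw
}
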