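# Shared fixtures: small cameras and hand-built phantoms keep the image
# tests fast; native-scale objects are built only where the geometry or
# the segmentation quality is itself under test.

small_camera <- function(h = 16L, w = 24L, read_noise_sd = 0) {
  camera_model(height = h, width = w, read_noise_sd = read_noise_sd)
}

# A phantom-shaped object with fully controlled contents (bypasses the
# generator so tests can pin exact reflectance values).
manual_phantom <- function(values, od = c(x = 2, y = 2), fovea = c(x = 10, y = 2),
                           vessels = NULL) {
  d <- dim(values)
  structure(list(
    height = d[1], width = d[2], od_center = od, fovea = fovea,
    eye = "right",
    vessel_truth = vessels %||% matrix(FALSE, d[1], d[2]),
    base_reflectance = values,
    band_centers = seq(465, 615, 10),
    subject_ref = "manual"
  ), class = "retinal_phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

uniform_cube <- function(value, h = 16L, w = 24L) {
  hyperspectral_cube(array(value, c(h, w, 16L)), seq(465, 615, 10))
}

# One subject row with controlled fields.
manual_subject <- function(group = "AD", load = 1, eye = "right",
                           id = "S1") {
  data.frame(subject_id = id, group = group, eye = eye,
             amyloid_load = load, stringsAsFactors = FALSE)
}

# Gaussian two-class feature matrix with a mean shift on given columns.
make_features <- function(n, p, shift = 0, shift_cols = seq_len(min(3, p)),
                          n_pos = floor(n / 2), seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(c("AD", "CTRL"), c(n_pos, n - n_pos))
  x[y == "AD", shift_cols] <- x[y == "AD", shift_cols] + shift
  list(x = x, y = y)
}
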