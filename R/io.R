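# File I/O: ENVI-style cubes, 16-bit TIFF raw frames, PNG masks,
# CSV/JSON tables.  The ENVI reader/writer is minimal on purpose: text
# header (samples/lines/bands, data type 4 = float32, band-sequential
# interleave, wavelength list) plus a little-endian binary payload.

#' Write a hyperspectral cube as ENVI header + binary
#'
#' @param cube A [hyperspectral_cube()].
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.hdr` and `<prefix>.img` (float32, band-sequential,
#'   little-endian).
#' @return `path_prefix`, invisibly.
#' @export
write_envi_cube <- function(cube, path_prefix) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {retispec hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf("wavelength units = Nanometers"),
    sprintf("wavelength = {%s}", paste(cube$band_centers, collapse = ", "))
  )
  writeLines(hdr, paste0(path_prefix, ".hdr"))
  con <- file(paste0(path_prefix, ".img"), "wb")
  on.exit(close(con))
  # BSQ: band-major; within a band row-major (line by line)
  for (b in seq_len(d[3])) {
    writeBin(as.numeric(t(cube$values[, , b])), con, size = 4,
             endian = "little")
  }
  invisible(path_prefix)
}

#' Read an ENVI-style cube written by [write_envi_cube()]
#'
#' @param path_prefix Path without extension.
#' @param subject_ref Optional subject id to attach.
#' @return A [hyperspectral_cube()].
#' @export
read_envi_cube <- function(path_prefix, subject_ref = NA_character_) {
  hdr <- readLines(paste0(path_prefix, ".hdr"))
  getval <- function(key) {
    ln <- grep(sprintf("^%s *=", key), hdr, value = TRUE)
    sub(sprintf("^%s *= *", key), "", ln[1])
  }
  samples <- as.integer(getval("samples"))
  lines_n <- as.integer(getval("lines"))
  bands <- as.integer(getval("bands"))
  if (as.integer(getval("data type")) != 4L ||
      tolower(getval("interleave")) != "bsq") {
    stop_retispec("only float32 band-sequential ENVI cubes are supported",
                  "retispec_io_error")
  }
  wl_txt <- paste(hdr[grep("wavelength *= *\\{", hdr):length(hdr)],
                  collapse = " ")
  wl_txt <- sub(".*\\{", "", sub("\\}.*", "", wl_txt))
  wl <- as.numeric(strsplit(wl_txt, ",")[[1]])
  con <- file(paste0(path_prefix, ".img"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = samples * lines_n * bands, size = 4,
                  endian = "little")
  cube <- array(0, dim = c(lines_n, samples, bands))
  per_band <- samples * lines_n
  for (b in seq_len(bands)) {
    cube[, , b] <- matrix(vals[((b - 1) * per_band + 1):(b * per_band)],
                          lines_n, samples, byrow = TRUE)
  }
  hyperspectral_cube(cube, wl, subject_ref)
}

#' Write a raw mosaic frame as 16-bit TIFF
#'
#' @param raw Raw frame matrix (DN in \[0, 65535\]).
#' @param path Output file path.
#' @export
write_raw_tiff <- function(raw, path) {
  tiff::writeTIFF(unclass(raw) / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a raw mosaic frame from 16-bit TIFF
#'
#' @param path TIFF path.
#' @return Integer DN matrix.
#' @export
read_raw_tiff <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

#' Write a boolean mask as PNG (0/255)
#' @param mask Logical matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a boolean mask from PNG
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  png::readPNG(path) > 0.5
}
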