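# Raster I/O: single-channel 16-bit TIFF by default, 8-bit PNG on
# request. Images are stored internally as integer grey-value matrices
# (see the package coordinate convention); files hold the same integers
# scaled to the format's [0, 1] range.

#' Write a grey-value image to TIFF or PNG
#'
#' @param image numeric matrix of integer grey values; bit depth is taken
#'   from its `bit_depth` attribute (default 16).
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  bits <- attr(image, "bit_depth")
  if (is.null(bits)) bits <- 16L
  maxval <- 2^bits - 1
  m <- unclass(image) / maxval
  attributes(m) <- list(dim = dim(image))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(m, path, bits.per.sample = as.integer(bits))
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (bits > 8) nq_error("nq_value_error", "PNG output supports 8-bit images")
    png::writePNG(m, path)
  } else {
    nq_error("nq_value_error", "unsupported image format (use .tif or .png)")
  }
  invisible(path)
}

#' Read a grey-value image from TIFF or PNG
#'
#' @param path input path.
#' @param bit_depth bit depth of the stored integers (default 16 for TIFF,
#'   8 for PNG).
#' @return integer grey-value matrix of class `nq_image`.
#' @export
read_image <- function(path, bit_depth = NULL) {
  if (!file.exists(path))
    nq_error("nq_io_error", paste("image file not found:", path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path)
    if (is.null(bit_depth)) bit_depth <- 16L
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path)
    if (is.null(bit_depth)) bit_depth <- 8L
  } else {
    nq_error("nq_io_error", "unsupported image format (use .tif or .png)")
  }
  if (length(dim(m)) == 3) m <- m[, , 1]
  img <- round(m * (2^bit_depth - 1))
  structure(img, bit_depth = as.integer(bit_depth),
            class = c("nq_image", class(img)))
}
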