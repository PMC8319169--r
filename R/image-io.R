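## Grayscale image input/output: PNG (8-bit), TIFF (16-bit) and plain
## whitespace-delimited numeric grids.  Images are stored in [0, 1] and
## converted to double-precision matrices on read; color inputs are
## averaged to luminance.

#' Read a grayscale image
#'
#' Supports PNG and TIFF (values scaled to `[0, 1]`; color channels
#' averaged) and plain text numeric grids (used verbatim).
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`, anything else is read as a text grid).
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    as.matrix(utils::read.table(path)))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  storage.mode(img) <- "double"
  unname(img)
}

#' Write a grayscale image
#'
#' Values are clamped to `[0, 1]`.  PNG is written at 8 bits, TIFF at 16
#' bits; any other extension writes a plain text grid (lossless).
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "tif", "tiff")) {
    img <- pmin(pmax(image, 0), 1)
    if (ext == "png") png::writePNG(img, path)
    else tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else {
    utils::write.table(image, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
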