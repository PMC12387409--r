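## PNG/TIFF image input and output.

#' Read a grayscale image
#'
#' Reads a PNG or TIFF file into a \[0, 1\] matrix.  Multi-channel images
#' are converted by luminance (with a notice); 8/16-bit integer files are
#' scaled by their dtype maximum by the readers.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix `[row, col]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  as_gray01(img)
}

#' Write a grayscale image
#'
#' Writes a numeric matrix to PNG (8-bit) or TIFF (16-bit).  Values are
#' clipped to \[0, 1\].
#'
#' @param image numeric matrix.
#' @param path output path; the extension selects the format.
#' @return invisibly, `path`.
#' @export
write_gray_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
         stop("unsupported image format: .", ext))
  invisible(path)
}
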