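# Image reading/writing and resizing.  Images are numeric arrays
# [rows, cols, 3] with values in [0, 1].

#' Read an overhead RGB image
#'
#' PNG and TIFF are supported.  Grey images are replicated to three
#' channels; an alpha channel is dropped.
#'
#' @param path image file
#' @return array `[H, W, 3]` in `[0, 1]`
#' @export
read_orchard_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image
#'
#' Format follows the file extension (`.png`, `.tif`/`.tiff`).
#'
#' @param image array `[H, W, 3]`, values clamped to `[0, 1]`
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_orchard_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(image, path) else png::writePNG(image, path)
  invisible(path)
}

#' Bilinearly resize an image or density map
#'
#' @param image array `[H, W, C]` or matrix
#' @param size target `(H, W)` (a single value means square)
#' @return resized array
#' @export
resize_image <- function(image, size) {
  if (length(size) == 1) size <- c(size, size)
  ismat <- is.matrix(image)
  if (ismat) image <- array(image, c(dim(image), 1))
  out <- EBImage::resize(image, w = size[1], h = size[2])
  out <- as.numeric(out)
  dim(out) <- c(size[1], size[2], dim(image)[3])
  if (ismat) out <- out[, , 1]
  out
}

# rescale point coordinates to follow resize_image (0-based pixel-center)
rescale_points <- function(points, from, to) {
  if (nrow(points) == 0) return(points)
  sy <- to[1] / from[1]; sx <- to[2] / from[2]
  points$x <- (points$x + 0.5) * sx - 0.5
  points$y <- (points$y + 0.5) * sy - 0.5
  points
}
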