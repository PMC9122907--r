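#' Read an 8-bit image
#'
#' Reads a PNG or TIFF image and returns intensities scaled to \[0, 1\].
#' Only 8-bit images are accepted; higher bit depths are rejected
#' explicitly.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @return H x W (grayscale) or H x W x C numeric array in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: '", path, "' does not exist")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8)
      stop("'", path, "' is ", info$bit.depth,
           "-bit; only 8-bit images are supported")
    attr(img, "info") <- NULL
    img
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits > 8)
      stop("'", path, "' is ", bits, "-bit; only 8-bit images are supported")
    attributes(img) <- list(dim = dim(img))
    img
  } else {
    stop("unsupported image format '", ext, "' for '", path,
         "'; use PNG or TIFF")
  }
}

#' Write an image / write a binary mask
#'
#' Masks are written as 0/255 8-bit PNG and round-trip exactly.
#'
#' @param image numeric array in \[0, 1\].
#' @param mask 0/1 matrix.
#' @param path output path (`.png`).
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("`mask` must be binary 0/1")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 mask PNG as a 0/1 matrix
#'
#' @param path file path.
#' @return Integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(img >= 0.5), nrow(img), ncol(img))
}
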