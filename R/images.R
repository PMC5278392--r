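#' Read an image as a 0-255 array
#'
#' Reads an 8-bit RGB or grayscale image (TIFF, PNG or JPEG) into the array
#' convention used throughout the package: rows x columns (x channels),
#' values in `[0, 255]`.
#'
#' @param path path to a TIFF, PNG or JPEG file.
#' @param pixel_size optional physical calibration in micrometres per pixel,
#'   stored as the `"pixel_size"` attribute of the returned array.
#' @return an `H x W x 3` array for colour images or an `H x W` matrix for
#'   grayscale images, values in `[0, 255]`.
#' @export
read_image <- function(path, pixel_size = NULL) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) {
    out <- t(dat) * 255
  } else {
    # EBImage stores (x, y, channel); keep at most 3 channels (drop alpha)
    dat <- dat[, , seq_len(min(dim(dat)[3], 3L)), drop = FALSE]
    if (dim(dat)[3] == 1L) {
      out <- t(dat[, , 1L]) * 255
    } else {
      out <- aperm(dat, c(2L, 1L, 3L)) * 255
    }
  }
  if (!is.null(pixel_size)) attr(out, "pixel_size") <- pixel_size
  out
}

#' Write a 0-255 array to an image file
#'
#' @param img `H x W x 3` array or `H x W` matrix, values in `[0, 255]`.
#' @param path output path; format chosen from the extension
#'   (.tif/.tiff/.png/.jpg/.jpeg).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  x <- pmin(pmax(img / 255, 0), 1)
  if (length(dim(x)) == 3L) {
    ebi <- EBImage::Image(aperm(x, c(2L, 1L, 3L)), colormode = "Color")
  } else {
    ebi <- EBImage::Image(t(x))
  }
  EBImage::writeImage(ebi, path)
  invisible(path)
}

# internal validators -------------------------------------------------------

assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(sprintf("`%s` has empty dimensions", arg), call. = FALSE)
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255)
    stop(sprintf("`%s` must have channel values in [0, 255]", arg),
         call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (is.logical(mask)) mask <- mask * 1
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a 2-D raster", arg),
                             call. = FALSE)
  mask
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(sprintf("%s must have the same shape", what), call. = FALSE)
  invisible(TRUE)
}
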