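# Raster filters shared by the IHC and bead pipelines. All wrap EBImage
# primitives; inputs are row x column matrices (binary masks may be logical).

ebi_median <- function(x, radius) {
  # EBImage::medianFilter needs values in [0, 1]
  was_logical <- is.logical(x)
  x <- x * 1
  s <- max(abs(x), 1)
  out <- EBImage::imageData(EBImage::medianFilter(x / s, radius)) * s
  if (was_logical) out <- out > 0.5
  out
}

#' Remove single-pixel noise (despeckle)
#'
#' One pass of a 3x3 median filter, the classical "Despeckle" step: isolated
#' single-pixel outliers are replaced by their neighbourhood median while
#' edges of larger structures are preserved.
#'
#' @param x a 2-D raster (grayscale matrix or binary mask).
#' @return a raster of the same type and shape.
#' @export
despeckle <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 2L)
    stop("`x` must be a 2-D raster", call. = FALSE)
  ebi_median(x, 1L)
}

#' Median filter with a given radius
#'
#' @param x a 2-D raster.
#' @param radius filter radius in pixels (2 reproduces the nuclear macro's
#'   "Median (2 px)" step).
#' @return filtered raster of the same shape.
#' @export
median_filter <- function(x, radius = 2) {
  if (is.null(dim(x)) || length(dim(x)) != 2L)
    stop("`x` must be a 2-D raster", call. = FALSE)
  ebi_median(x, as.integer(radius))
}

#' Morphological opening (minimum then maximum filter)
#'
#' Erosion followed by dilation with a disk structuring element — the
#' "Minimum (2 px)" + "Maximum (2 px)" speck-removal step. Objects thinner
#' than twice the radius vanish; larger objects keep their area up to corner
#' rounding, and the result's foreground area never exceeds the input's.
#'
#' @param mask binary mask (logical or 0/1 matrix).
#' @param radius structuring-element radius in pixels (default 2).
#' @return logical mask of the same shape.
#' @export
morpho_clean <- function(mask, radius = 2) {
  m <- assert_mask(mask)
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::imageData(EBImage::opening(m, brush)) > 0.5
}

# iterative intermeans ("isodata"/ImageJ Default) threshold on raw values
isodata_threshold <- function(x, tol = 1e-7, max_iter = 200L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (!is.finite(rng[1]) || diff(rng) < 1e-12)
    stop("degenerate threshold: raster is constant; use a fixed threshold",
         call. = FALSE)
  t0 <- mean(rng)
  for (i in seq_len(max_iter)) {
    lo <- v[v < t0]; hi <- v[v >= t0]
    if (!length(lo) || !length(hi)) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < tol) return(t1)
    t0 <- t1
  }
  t0
}

#' Threshold a stain-density (or intensity) plane
#'
#' Produces a binary mask `map >= threshold`. The automatic `"isodata"`
#' method is the iterative-intermeans rule behind the common "Default"
#' threshold; `"otsu"` maximises between-class variance; `"fixed"` uses a
#' supplied value (for screen-to-screen reproducibility). The threshold
#' actually applied is recorded on the result so it can be logged with every
#' measurement.
#'
#' @param map 2-D numeric raster (typically one plane of a deconvolved
#'   stain-density array).
#' @param method `"isodata"` (default), `"otsu"` or `"fixed"`.
#' @param value threshold value, required for `method = "fixed"`.
#' @return logical mask with attributes `threshold` and `method`.
#' @export
threshold_channel <- function(map, method = c("isodata", "otsu", "fixed"),
                              value = NULL) {
  method <- match.arg(method)
  if (is.null(dim(map)) || length(dim(map)) != 2L)
    stop("`map` must be a 2-D raster", call. = FALSE)
  thr <- switch(method,
    fixed = {
      if (is.null(value)) stop("fixed method requires `value`", call. = FALSE)
      value
    },
    isodata = isodata_threshold(map),
    otsu = {
      rng <- range(map)
      if (diff(rng) < 1e-12)
        stop("degenerate threshold: raster is constant; use a fixed threshold",
             call. = FALSE)
      scaled <- (map - rng[1]) / diff(rng)
      t01 <- EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1),
                           levels = 256L)
      rng[1] + t01 * diff(rng)
    })
  mask <- map >= thr
  attr(mask, "threshold") <- thr
  attr(mask, "method") <- method
  mask
}

#' Correct uneven background illumination
#'
#' Flat-field correction in the retrospective (pseudo-flat-field) style:
#' each channel is divided by a smooth gain field and rescaled so the gain
#' field maps to its own channel-wise median. With a recorded blank-field
#' image the gain is the (lightly smoothed) blank; without one, the gain is
#' estimated from the image itself by a large-radius Gaussian blur.
#'
#' @param img `H x W x 3` RGB array.
#' @param blank_field optional blank-field exposure of the same shape.
#' @param blank_sigma Gaussian sigma (px) used to smooth a supplied blank
#'   field (default 2; 0 uses the blank as-is).
#' @param sigma Gaussian sigma for self-estimation when no blank is given;
#'   default `min(H, W) / 8`.
#' @return corrected RGB array, clipped to `[0, 255]`.
#' @export
correct_background <- function(img, blank_field = NULL, blank_sigma = 2,
                               sigma = NULL) {
  assert_rgb(img)
  d <- dim(img)
  out <- img
  if (!is.null(blank_field)) {
    assert_rgb(blank_field, "blank_field")
    assert_same_shape(img, blank_field, "image and blank field")
    for (c in 1:3) {
      g <- if (blank_sigma > 0)
        EBImage::imageData(EBImage::gblur(blank_field[, , c], blank_sigma))
      else blank_field[, , c]
      if (min(g) <= 0)
        stop("degenerate blank field: zero intensity after smoothing",
             call. = FALSE)
      out[, , c] <- img[, , c] / g * median(g)
    }
  } else {
    if (is.null(sigma)) sigma <- min(d[1], d[2]) / 8
    for (c in 1:3) {
      g <- EBImage::imageData(EBImage::gblur(img[, , c], sigma))
      g <- pmax(g, 1e-6)
      out[, , c] <- img[, , c] / g * median(g)
    }
  }
  out <- pmin(pmax(out, 0), 255)
  dim(out) <- d
  out
}

#' Find the common content rectangle of an image stack
#'
#' Computes the minimum projection over all images (and channels), separates
#' content (dark) from background with an isodata threshold, and returns the
#' bounding rectangle of all content pixels — the automated counterpart of
#' "minimum Z-projection, then crop". When no content is found the full
#' frame is returned with `warning = TRUE`.
#'
#' @param images a single RGB/grayscale array or a list of same-shaped ones.
#' @return an object of class `crop_rect`: list with `rows` and `cols`
#'   (1-based inclusive index ranges) and a `warning` flag.
#' @export
crop_to_content <- function(images) {
  if (!is.list(images)) images <- list(images)
  if (!length(images)) stop("no images supplied", call. = FALSE)
  proj <- NULL
  for (im in images) {
    flat <- if (length(dim(im)) == 3L) apply(im, c(1, 2), min) else im * 1
    if (is.null(proj)) proj <- flat
    else {
      assert_same_shape(proj, flat, "images in the stack")
      proj <- pmin(proj, flat)
    }
  }
  warn <- FALSE
  fg <- tryCatch(proj < isodata_threshold(proj), error = function(e) NULL)
  if (is.null(fg) || !any(fg)) {
    warn <- TRUE
    rows <- c(1L, nrow(proj)); cols <- c(1L, ncol(proj))
  } else {
    rows <- range(which(rowSums(fg) > 0))
    cols <- range(which(colSums(fg) > 0))
  }
  structure(list(rows = rows, cols = cols, warning = warn),
            class = "crop_rect")
}

#' Apply a crop rectangle to an image
#'
#' @param img RGB array or grayscale matrix.
#' @param rect a `crop_rect` from [crop_to_content()].
#' @return the cropped image.
#' @export
apply_crop <- function(img, rect) {
  stopifnot(inherits(rect, "crop_rect"))
  if (length(dim(img)) == 3L)
    img[rect$rows[1]:rect$rows[2], rect$cols[1]:rect$cols[2], , drop = FALSE]
  else
    img[rect$rows[1]:rect$rows[2], rect$cols[1]:rect$cols[2], drop = FALSE]
}

#' Draw quality-control outlines on an image
#'
#' Overlays 1-px outer contours: green `(0, 255, 0)` around the recognised
#' tissue and magenta `(255, 0, 255)` around the positive areas, magenta
#' drawn last so it wins where contours overlap. The outer contour of a mask
#' is its dilation by a 3x3 box minus the mask itself.
#'
#' @param img `H x W x 3` RGB array.
#' @param tissue_mask,positive_mask binary masks of the same shape as `img`.
#' @return RGB array with outlines burned in.
#' @export
make_qc_overlay <- function(img, tissue_mask, positive_mask) {
  assert_rgb(img)
  tissue_mask <- assert_mask(tissue_mask) > 0
  positive_mask <- assert_mask(positive_mask) > 0
  assert_same_shape(img, tissue_mask, "image and tissue mask")
  assert_same_shape(img, positive_mask, "image and positive mask")
  out <- img
  paint <- function(out, mask, colour) {
    if (!any(mask)) return(out)
    box <- matrix(1, 3, 3)
    contour <- (EBImage::imageData(EBImage::dilate(mask * 1, box)) > 0.5) & !mask
    for (c in 1:3) {
      plane <- out[, , c]
      plane[contour] <- colour[c]
      out[, , c] <- plane
    }
    out
  }
  out <- paint(out, tissue_mask, c(0, 255, 0))
  out <- paint(out, positive_mask, c(255, 0, 255))
  out
}
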