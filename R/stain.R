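#' Published H-DAB stain absorbance vectors
#'
#' Unit-norm optical-density vectors for hematoxylin and DAB in RGB space,
#' as published by Ruifrok and Johnston and shipped as the "H DAB" preset of
#' the common colour-deconvolution implementations. Used as the package-wide
#' default stain system; override by building a [stain_system()] from
#' measured vectors when the staining chemistry differs.
#'
#' @format a list with numeric 3-vectors `h` and `dab` (R, G, B order).
#' @export
hdab_vectors <- list(
  h   = c(0.650, 0.704, 0.286),
  dab = c(0.268, 0.570, 0.776)
)

#' Build a stain system for colour deconvolution
#'
#' Assembles the 3x3 stain matrix used by Beer-Lambert colour deconvolution.
#' Rows are the unit-norm optical-density vectors of hematoxylin, DAB and a
#' residual third "stain" completed as the normalised cross product of the
#' first two, so that the matrix is always invertible for non-collinear
#' inputs.
#'
#' @param h_vector,dab_vector numeric 3-vectors of per-channel optical
#'   densities (R, G, B) for hematoxylin and DAB. Defaults are the published
#'   H-DAB pair in [hdab_vectors].
#' @return an object of class `stain_system`: a list with `vectors` (3x3,
#'   rows H, DAB, residual, each unit Euclidean norm) and `inverse` (3x3,
#'   satisfying `inverse %*% t(vectors) = I`).
#' @examples
#' sys <- stain_system()
#' sys$inverse %*% t(sys$vectors)  # identity
#' @export
stain_system <- function(h_vector = hdab_vectors$h,
                         dab_vector = hdab_vectors$dab) {
  h_vector <- as.numeric(h_vector)
  dab_vector <- as.numeric(dab_vector)
  if (length(h_vector) != 3L || length(dab_vector) != 3L)
    stop("stain vectors must have length 3", call. = FALSE)
  nh <- sqrt(sum(h_vector^2)); nd <- sqrt(sum(dab_vector^2))
  if (nh == 0 || nd == 0)
    stop("singular stain system: zero stain vector", call. = FALSE)
  h <- h_vector / nh
  d <- dab_vector / nd
  res <- c(h[2] * d[3] - h[3] * d[2],
           h[3] * d[1] - h[1] * d[3],
           h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(res^2))
  if (nr < 1e-12)
    stop("singular stain system: collinear stain vectors", call. = FALSE)
  v <- rbind(h = h, dab = d, residual = res / nr)
  colnames(v) <- c("r", "g", "b")
  inv <- solve(t(v))
  if (max(abs(inv %*% t(v) - diag(3))) > 1e-9)
    stop("singular stain system: inversion failed", call. = FALSE)
  structure(list(vectors = v, inverse = inv), class = "stain_system")
}

#' @export
print.stain_system <- function(x, ...) {
  cat("Stain system (rows = unit OD vectors):\n")
  print(round(x$vectors, 4))
  invisible(x)
}

#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert transform channel-wise:
#' `OD = -log10(max(I, 1) / I0)`. Intensities below 1 are clamped to 1 so
#' the transform stays finite on saturated dark pixels.
#'
#' @param img `H x W x 3` RGB array, values in `[0, 255]`.
#' @param background_intensity incident ("white") intensity `I0`; defaults
#'   to 255 for plain 8-bit images, configurable for flat-field-corrected
#'   input.
#' @return `H x W x 3` array of optical densities.
#' @export
rgb_to_od <- function(img, background_intensity = 255) {
  assert_rgb(img)
  if (!is.numeric(background_intensity) || length(background_intensity) != 1L ||
      background_intensity <= 0)
    stop("`background_intensity` must be a positive scalar", call. = FALSE)
  od <- -log10(pmax(img, 1) / background_intensity)
  dim(od) <- dim(img)
  od
}

#' Separate stains by colour deconvolution
#'
#' Linearly unmixes per-pixel optical densities into per-stain density maps
#' using the inverse of the stain matrix (Ruifrok-Johnston colour
#' deconvolution). Slightly negative densities arising from noise are kept
#' as-is; masking and clipping are downstream display decisions.
#'
#' @param od `H x W x 3` optical-density array from [rgb_to_od()].
#' @param system a [stain_system()].
#' @return `H x W x 3` array of stain densities, planes ordered
#'   (hematoxylin, DAB, residual).
#' @export
deconvolve <- function(od, system = stain_system()) {
  if (!inherits(system, "stain_system")) stop("`system` must be a stain_system",
                                              call. = FALSE)
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    stop("`od` must be an H x W x 3 array", call. = FALSE)
  d <- dim(od)
  m <- matrix(od, ncol = 3L)        # pixels x channels
  maps <- m %*% t(system$inverse)   # pixels x stains
  array(maps, dim = d, dimnames = list(NULL, NULL, rownames(system$vectors)))
}

#' Synthesize an RGB image from stain density maps
#'
#' Forward Beer-Lambert model, the inverse of [deconvolve()] plus
#' quantisation: `I_c = I0 * 10^-(maps . vectors)_c`, rounded to the nearest
#' integer in `[0, 255]`. This is the renderer used by the synthetic-fixture
#' generators, so deconvolution can be validated by round trip.
#'
#' @param maps `H x W x 3` nonnegative stain density array (H, DAB,
#'   residual).
#' @param system a [stain_system()].
#' @param background_intensity incident intensity `I0` (default 255).
#' @return `H x W x 3` RGB array of integers in `[0, 255]`.
#' @export
synthesize_rgb <- function(maps, system = stain_system(),
                           background_intensity = 255) {
  if (!inherits(system, "stain_system")) stop("`system` must be a stain_system",
                                              call. = FALSE)
  if (!is.array(maps) || length(dim(maps)) != 3L || dim(maps)[3] != 3L)
    stop("`maps` must be an H x W x 3 array", call. = FALSE)
  if (min(maps) < 0) stop("`maps` must be nonnegative", call. = FALSE)
  d <- dim(maps)
  od <- matrix(maps, ncol = 3L) %*% system$vectors   # pixels x channels
  img <- round(background_intensity * 10^(-od))
  img <- pmin(pmax(img, 0), 255)
  array(img, dim = d)
}
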