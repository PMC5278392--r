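#' Quantify a cytoplasmic stain as percent positive area
#'
#' The cytoplasmic readout divides the DAB-positive area by the
#' hematoxylin-positive (tissue) area. DAB outside the tissue mask is
#' treated as artefact: the positive area is intersected with the tissue
#' area before division, so the percentage is bounded by 100.
#'
#' @param tissue_mask binary mask of hematoxylin-positive tissue.
#' @param dab_mask binary mask of DAB-positive staining.
#' @param pixel_size optional micrometres per pixel; when given, areas are
#'   also reported in square micrometres.
#' @return an object of class `cyto_result`: tissue and DAB areas (px and,
#'   when calibrated, um^2), `percent_positive`, and the thresholds recorded
#'   on the input masks (if any).
#' @export
quantify_cytoplasmic <- function(tissue_mask, dab_mask, pixel_size = NULL) {
  tm <- assert_mask(tissue_mask) > 0
  dm <- assert_mask(dab_mask) > 0
  assert_same_shape(tm, dm, "masks")
  tissue_px <- sum(tm)
  if (tissue_px == 0) stop("no tissue: empty tissue mask", call. = FALSE)
  dab_px <- sum(dm & tm)
  res <- list(
    tissue_area_px = tissue_px,
    dab_area_px = dab_px,
    tissue_area_um2 = if (!is.null(pixel_size)) tissue_px * pixel_size^2,
    dab_area_um2 = if (!is.null(pixel_size)) dab_px * pixel_size^2,
    percent_positive = 100 * dab_px / tissue_px,
    h_threshold = attr(tissue_mask, "threshold"),
    dab_threshold = attr(dab_mask, "threshold")
  )
  structure(res, class = "cyto_result")
}

#' @export
print.cyto_result <- function(x, ...) {
  cat(sprintf("Cytoplasmic stain: %.2f%% positive (DAB %d / tissue %d px)\n",
              x$percent_positive, x$dab_area_px, x$tissue_area_px))
  invisible(x)
}

#' Segment nuclei in a binary mask
#'
#' Runs the nuclear-macro pipeline on a thresholded nuclei mask: despeckle,
#' median filter (radius 2), minimum/maximum opening (radius 2), then
#' watershed on the Euclidean distance transform (with 1-px h-maxima
#' suppression) to split touching nuclei, and finally a minimum-area filter.
#'
#' @param mask binary nuclei mask.
#' @param min_area minimum nucleus area in square micrometres (default 20);
#'   smaller objects are discarded.
#' @param pixel_size micrometres per pixel; required so `min_area` can be
#'   converted to pixels.
#' @param clean apply the despeckle/median/opening clean-up before watershed
#'   (default `TRUE`).
#' @return an object of class `nuclei_labels`: list with `labels` (integer
#'   raster, 0 = background), `count`, and the `min_area`/`pixel_size` used.
#' @export
segment_nuclei <- function(mask, min_area = 20, pixel_size = NULL,
                           clean = TRUE) {
  m <- assert_mask(mask) > 0
  if (!is.numeric(min_area) || min_area <= 0)
    stop("`min_area` must be > 0", call. = FALSE)
  if (is.null(pixel_size))
    stop("calibration error: `pixel_size` (um/px) is required to apply ",
         "`min_area` in um^2", call. = FALSE)
  if (clean && any(m)) {
    m <- despeckle(m) > 0.5
    m <- median_filter(m, 2) > 0.5
    m <- morpho_clean(m, 2)
  }
  if (!any(m)) {
    labels <- matrix(0L, nrow(m), ncol(m))
    return(structure(list(labels = labels, count = 0L, min_area = min_area,
                          pixel_size = pixel_size), class = "nuclei_labels"))
  }
  dist <- EBImage::distmap(m * 1)
  labels <- EBImage::imageData(EBImage::watershed(dist, tolerance = 1, ext = 1))
  labels <- matrix(as.integer(labels), nrow(m), ncol(m))
  # minimum-area filter in physical units
  min_px <- min_area / pixel_size^2
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_px)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  labels[labels > 0] <- relab[labels[labels > 0]]
  structure(list(labels = labels, count = length(keep), min_area = min_area,
                 pixel_size = pixel_size), class = "nuclei_labels")
}

#' @export
print.nuclei_labels <- function(x, ...) {
  cat(sprintf("%d nuclei (min area %.1f um^2 at %.2f um/px)\n",
              x$count, x$min_area, x$pixel_size))
  invisible(x)
}

#' Quantify a nuclear stain as percent positive nuclei
#'
#' Counts DAB-positive and total nuclei with [segment_nuclei()] and reports
#' their ratio. Two denominator conventions are available:
#'
#' * `"union"` (default): total nuclei are counted on the union of the H
#'   and DAB masks, because strong DAB deposition can quench the
#'   hematoxylin counterstain; the percentage is capped at 100.
#' * `"h-only"`: the literal ratio of DAB-positive to
#'   hematoxylin-positive nuclei, uncapped.
#'
#' @param h_mask binary mask of hematoxylin-positive nuclei.
#' @param dab_mask binary mask of DAB-positive nuclei.
#' @param min_area,pixel_size passed to [segment_nuclei()].
#' @param mode denominator convention, `"union"` or `"h-only"`.
#' @return an object of class `nuclear_result` with counts
#'   `n_nuclei_h` (denominator), `n_nuclei_dab`, and `percent_positive`.
#' @export
quantify_nuclear <- function(h_mask, dab_mask, min_area = 20,
                             pixel_size = NULL,
                             mode = c("union", "h-only")) {
  mode <- match.arg(mode)
  hm <- assert_mask(h_mask) > 0
  dm <- assert_mask(dab_mask) > 0
  assert_same_shape(hm, dm, "masks")
  denom_mask <- if (mode == "union") hm | dm else hm
  seg_h <- segment_nuclei(denom_mask, min_area, pixel_size)
  seg_d <- segment_nuclei(dm, min_area, pixel_size)
  if (seg_h$count == 0) stop("no nuclei detected in the denominator mask",
                             call. = FALSE)
  pct <- 100 * seg_d$count / seg_h$count
  if (mode == "union") pct <- min(pct, 100)
  structure(list(n_nuclei_h = seg_h$count, n_nuclei_dab = seg_d$count,
                 percent_positive = pct, mode = mode, min_area = min_area),
            class = "nuclear_result")
}

#' @export
print.nuclear_result <- function(x, ...) {
  cat(sprintf("Nuclear stain: %.2f%% positive (%d DAB+ / %d nuclei, %s mode)\n",
              x$percent_positive, x$n_nuclei_dab, x$n_nuclei_h, x$mode))
  invisible(x)
}

# full image-to-result pipelines -------------------------------------------

#' Cytoplasmic-stain analysis of one RGB section image
#'
#' Convenience pipeline: optical density, colour deconvolution, thresholding
#' of the H (tissue) and DAB planes, speck clean-up, and the percent
#' positive area readout.
#'
#' @param img `H x W x 3` RGB array.
#' @param system a [stain_system()].
#' @param h_method,dab_method threshold methods for the two planes (see
#'   [threshold_channel()]). The hematoxylin (tissue) threshold defaults to
#'   automatic isodata; the DAB threshold defaults to a fixed optical
#'   density of 0.2, standing in for the cutoff an analyst calibrates on
#'   positive and negative control sections — an automatic rule is unsound
#'   on negative images, which contain no DAB mode to find.
#' @param h_value,dab_value fixed thresholds when the respective method is
#'   `"fixed"`.
#' @param pixel_size optional um/px for areas in um^2.
#' @param background_intensity incident intensity for [rgb_to_od()].
#' @param clean apply despeckle + opening (radius 2) to both masks.
#' @return a `cyto_result`; the masks used are attached as attributes
#'   `tissue_mask` and `dab_mask` for QC rendering.
#' @export
analyze_cytoplasmic <- function(img, system = stain_system(),
                                h_method = "isodata", dab_method = "fixed",
                                h_value = NULL, dab_value = 0.2,
                                pixel_size = NULL, background_intensity = 255,
                                clean = TRUE) {
  od <- rgb_to_od(img, background_intensity)
  maps <- deconvolve(od, system)
  h_mask <- threshold_channel(maps[, , 1], h_method, h_value)
  dab_mask <- threshold_channel(maps[, , 2], dab_method, dab_value)
  h_clean <- h_mask
  dab_clean <- dab_mask
  if (clean) {
    h_clean <- morpho_clean(despeckle(h_mask) > 0.5, 2)
    dab_clean <- morpho_clean(despeckle(dab_mask) > 0.5, 2)
    attributes(h_clean)$threshold <- attr(h_mask, "threshold")
    attributes(dab_clean)$threshold <- attr(dab_mask, "threshold")
  }
  tissue <- h_clean
  attr(tissue, "threshold") <- attr(h_mask, "threshold")
  res <- quantify_cytoplasmic(tissue, dab_clean, pixel_size)
  attr(res, "tissue_mask") <- tissue
  attr(res, "dab_mask") <- dab_clean & tissue
  res
}

#' Nuclear-stain analysis of one RGB section image
#'
#' Pipeline for nuclear markers: optical density, colour deconvolution,
#' thresholding of the H and DAB planes, then watershed nucleus counting
#' via [quantify_nuclear()].
#'
#' @inheritParams analyze_cytoplasmic
#' @param min_area minimum nucleus area (um^2).
#' @param mode denominator convention, see [quantify_nuclear()].
#' @return a `nuclear_result` with masks attached as attributes
#'   `h_mask` and `dab_mask`.
#' @export
analyze_nuclear <- function(img, system = stain_system(),
                            h_method = "isodata", dab_method = "fixed",
                            h_value = NULL, dab_value = 0.2,
                            min_area = 20, pixel_size = 1,
                            background_intensity = 255,
                            mode = c("union", "h-only")) {
  mode <- match.arg(mode)
  od <- rgb_to_od(img, background_intensity)
  maps <- deconvolve(od, system)
  h_mask <- threshold_channel(maps[, , 1], h_method, h_value)
  dab_mask <- threshold_channel(maps[, , 2], dab_method, dab_value)
  res <- quantify_nuclear(h_mask, dab_mask, min_area, pixel_size, mode)
  res$h_threshold <- attr(h_mask, "threshold")
  res$dab_threshold <- attr(dab_mask, "threshold")
  attr(res, "h_mask") <- h_mask
  attr(res, "dab_mask") <- dab_mask
  res
}
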