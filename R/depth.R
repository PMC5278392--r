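#' Detect embedded beads in a cross-section image
#'
#' Reproduces the bead-particle analysis used to measure embedding-depth
#' uniformity: the grayscale side-view image is thresholded (isodata, the
#' "Default" rule), despeckled, opened with a radius-2 minimum/maximum
#' filter, and connected components with area above `min_area` are kept.
#' Each bead's lower edge is the physical depth of its bottom-most occupied
#' row (bounding-box top + height, times the pixel size).
#'
#' @param img grayscale matrix; beads darker than background.
#' @param pixel_size micrometres per pixel (the reference calibration is
#'   25 um/px).
#' @param min_area minimum particle area in um^2 (default 10000).
#' @param row_id identifier of the mold row this image sections.
#' @return a data frame with one row per bead: `row_id`, `area_um2`,
#'   `lower_edge_y` (um). Zero rows (with a warning) when nothing survives
#'   the filters.
#' @export
detect_beads <- function(img, pixel_size = 25, min_area = 10000, row_id = 1L) {
  if (is.null(dim(img)) || length(dim(img)) != 2L)
    stop("`img` must be a grayscale matrix", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be > 0", call. = FALSE)
  empty <- data.frame(row_id = integer(), area_um2 = numeric(),
                      lower_edge_y = numeric())
  mask <- tryCatch(img < isodata_threshold(img), error = function(e) NULL)
  if (is.null(mask) || !any(mask)) {
    warning("no beads detected", call. = FALSE)
    return(empty)
  }
  mask <- despeckle(mask) > 0.5
  mask <- morpho_clean(mask, 2)
  if (!any(mask)) {
    warning("no beads detected after filtering", call. = FALSE)
    return(empty)
  }
  labels <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  labels <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  sizes <- tabulate(labels)
  areas <- sizes * pixel_size^2
  keep <- which(areas >= min_area)
  if (!length(keep)) {
    warning("no beads above the minimum area", call. = FALSE)
    return(empty)
  }
  lower <- vapply(keep, function(k) {
    max(which(rowSums(labels == k) > 0)) * pixel_size
  }, numeric(1))
  data.frame(row_id = rep(as.integer(row_id), length(keep)),
             area_um2 = areas[keep], lower_edge_y = lower)
}

#' Summarise bead lower-edge deviations from the per-row median plane
#'
#' For each mold row, the common embedding plane is the median lower edge of
#' that row's beads; each bead's deviation is its lower edge minus the plane
#' (negative = above the plane). Deviations are pooled across rows and
#' summarised with a 50-um histogram centred on zero, the interquartile
#' range and the 10th/90th percentiles (linear-interpolation quantiles).
#'
#' @param detections data frame with columns `row_id` and `lower_edge_y`
#'   (um), e.g. rows bound from [detect_beads()] calls.
#' @param bin_width histogram bin width in um (default 50).
#' @return an object of class `depth_summary`: `deviations` (um),
#'   `iqr`, `p10_p90`, `histogram` (`breaks`, `counts`), `n_beads`.
#' @export
deviations_from_median_plane <- function(detections, bin_width = 50) {
  if (is.null(detections) || !nrow(detections))
    stop("no bead detections supplied", call. = FALSE)
  if (!all(c("row_id", "lower_edge_y") %in% names(detections)))
    stop("`detections` needs columns row_id and lower_edge_y", call. = FALSE)
  dev <- unlist(lapply(split(detections$lower_edge_y, detections$row_id),
                       function(y) y - median(y)), use.names = FALSE)
  half <- bin_width / 2
  lim <- max(abs(dev), half)
  nbins <- ceiling((lim - half) / bin_width)
  breaks <- seq(-half - nbins * bin_width, half + nbins * bin_width,
                by = bin_width)
  counts <- as.integer(table(cut(dev, breaks, include.lowest = TRUE)))
  structure(list(
    deviations = dev,
    iqr = unname(quantile(dev, c(0.25, 0.75), type = 7)),
    p10_p90 = unname(quantile(dev, c(0.10, 0.90), type = 7)),
    histogram = list(breaks = breaks, counts = counts,
                     bin_width = bin_width),
    n_beads = length(dev)
  ), class = "depth_summary")
}

#' @export
print.depth_summary <- function(x, ...) {
  cat(sprintf(
    "Embedding depth: %d beads; IQR %.0f to %.0f um; P10/P90 %.0f to %.0f um\n",
    x$n_beads, x$iqr[1], x$iqr[2], x$p10_p90[1], x$p10_p90[2]))
  invisible(x)
}

#' Plot a depth-deviation histogram
#'
#' @param x a `depth_summary`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.depth_summary <- function(x, ...) {
  h <- x$histogram
  mids <- head(h$breaks, -1) + h$bin_width / 2
  graphics::barplot(h$counts, names.arg = mids, space = 0,
                    xlab = "Deviation from median plane (um)",
                    ylab = "Beads", ...)
  invisible(x)
}
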