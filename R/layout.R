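#' Spheroid microarray layout
#'
#' Geometry of the array grid produced by the agarose mold: by default 66
#' wells in 6 rows and 11 columns, with the last column reserved for marker
#' wells that orient the grid.
#'
#' @param n_rows,n_cols grid dimensions (defaults 6 and 11).
#' @param pitch centre-to-centre well spacing in um; either a scalar or
#'   `c(x, y)`. The physical pitch depends on the mold, so it must be set
#'   for physical-unit work.
#' @param origin `(x, y)` position (um) of the well in row 1, column 1.
#' @param marker_columns integer column indices reserved for marker wells
#'   (default: the last column).
#' @return an object of class `array_layout` with a `capacity` field
#'   (`n_rows * n_cols`).
#' @export
array_layout <- function(n_rows = 6, n_cols = 11, pitch = 2000,
                         origin = c(0, 0), marker_columns = n_cols) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be >= 1",
                                     call. = FALSE)
  pitch <- rep(as.numeric(pitch), length.out = 2L)
  if (any(pitch <= 0)) stop("config error: pitch must be > 0", call. = FALSE)
  if (any(marker_columns < 1 | marker_columns > n_cols))
    stop("marker_columns must lie within 1..n_cols", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch = pitch, origin = as.numeric(origin),
                 marker_columns = as.integer(marker_columns),
                 capacity = as.integer(n_rows) * as.integer(n_cols)),
            class = "array_layout")
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("Array layout: %d x %d (%d wells), pitch %g x %g um\n",
              x$n_rows, x$n_cols, x$capacity, x$pitch[1], x$pitch[2]))
  invisible(x)
}

layout_nodes <- function(layout, origin = layout$origin) {
  grid <- expand.grid(row = seq_len(layout$n_rows),
                      col = seq_len(layout$n_cols))
  grid$x <- origin[1] + (grid$col - 1) * layout$pitch[1]
  grid$y <- origin[2] + (grid$row - 1) * layout$pitch[2]
  grid
}

#' Assign detected spots to array wells (de-arraying)
#'
#' Maps spot centroids to the nearest grid node. Spots farther than
#' `tolerance` from every node stay unassigned; when several spots compete
#' for one well the smallest residual wins and the others are unassigned
#' (strict one-spot-per-well), except in wells of `marker_columns` when
#' `permissive_markers` is set, since marker wells legitimately hold
#' multiple spheroids.
#'
#' @param centroids two-column matrix or data frame of spot `(x, y)`
#'   positions in um.
#' @param layout an [array_layout()].
#' @param tolerance maximum assignment residual in um; must be below half
#'   the pitch. Default `0.45 * min(pitch)`.
#' @param estimate_origin re-estimate the grid origin from the centroids
#'   (median offset after a provisional assignment), making the mapping
#'   invariant to global translation of the slide.
#' @param permissive_markers allow multiple spots per marker-column well.
#' @return data frame with one row per spot: `spot`, `x`, `y`, `row`,
#'   `col` (NA when unassigned) and `residual` (um).
#' @export
assign_spots <- function(centroids, layout, tolerance = NULL,
                         estimate_origin = FALSE,
                         permissive_markers = FALSE) {
  stopifnot(inherits(layout, "array_layout"))
  cen <- as.matrix(centroids)[, 1:2, drop = FALSE]
  if (is.null(tolerance)) tolerance <- 0.45 * min(layout$pitch)
  if (tolerance >= min(layout$pitch) / 2)
    stop("tolerance must be below half the pitch", call. = FALSE)
  origin <- layout$origin
  if (estimate_origin && nrow(cen) >= 3) {
    # centre the grid on the spot cloud, then refine by the median offset
    ctr <- c(mean(range(cen[, 1])), mean(range(cen[, 2])))
    origin <- ctr - c((layout$n_cols - 1) / 2 * layout$pitch[1],
                      (layout$n_rows - 1) / 2 * layout$pitch[2])
    for (i in 1:3) {
      col <- pmin(pmax(round((cen[, 1] - origin[1]) / layout$pitch[1]) + 1, 1),
                  layout$n_cols)
      row <- pmin(pmax(round((cen[, 2] - origin[2]) / layout$pitch[2]) + 1, 1),
                  layout$n_rows)
      off <- cbind(cen[, 1] - (origin[1] + (col - 1) * layout$pitch[1]),
                   cen[, 2] - (origin[2] + (row - 1) * layout$pitch[2]))
      origin <- origin + c(median(off[, 1]), median(off[, 2]))
    }
  }
  col <- round((cen[, 1] - origin[1]) / layout$pitch[1]) + 1
  row <- round((cen[, 2] - origin[2]) / layout$pitch[2]) + 1
  nx <- origin[1] + (col - 1) * layout$pitch[1]
  ny <- origin[2] + (row - 1) * layout$pitch[2]
  residual <- sqrt((cen[, 1] - nx)^2 + (cen[, 2] - ny)^2)
  ok <- residual <= tolerance & col >= 1 & col <= layout$n_cols &
    row >= 1 & row <= layout$n_rows
  out <- data.frame(spot = seq_len(nrow(cen)), x = cen[, 1], y = cen[, 2],
                    row = ifelse(ok, row, NA_integer_),
                    col = ifelse(ok, col, NA_integer_),
                    residual = residual)
  # conflict resolution: smallest residual keeps the well
  assigned <- which(!is.na(out$row))
  if (length(assigned) > 1) {
    ord <- assigned[order(out$residual[assigned])]
    seen <- character()
    for (i in ord) {
      key <- paste(out$row[i], out$col[i])
      multi_ok <- permissive_markers && out$col[i] %in% layout$marker_columns
      if (key %in% seen && !multi_ok) {
        out$row[i] <- NA_integer_
        out$col[i] <- NA_integer_
      } else seen <- c(seen, key)
    }
  }
  out
}

#' Sections available in the central band of a spheroid
#'
#' Number of contiguous sections of a given thickness that fit in the band
#' extending a fraction of the diameter above and below the equatorial
#' midline: `floor(2 * band_fraction * diameter / thickness)`. For a 500-um
#' spheroid, 4-um sections and a 20% band this is 50 sections.
#'
#' @param diameter spheroid diameter (um).
#' @param band_fraction fraction of the diameter on each side of the
#'   midline, in `[0, 0.5]`.
#' @param thickness section thickness (um).
#' @return integer section count.
#' @export
sections_in_center_band <- function(diameter, band_fraction, thickness) {
  if (!is.numeric(diameter) || diameter <= 0)
    stop("`diameter` must be > 0", call. = FALSE)
  if (!is.numeric(band_fraction) || band_fraction < 0 || band_fraction > 0.5)
    stop("`band_fraction` must be in [0, 0.5]", call. = FALSE)
  if (!is.numeric(thickness) || thickness <= 0)
    stop("invalid parameter: `thickness` must be > 0", call. = FALSE)
  as.integer(floor(2 * band_fraction * diameter / thickness))
}

#' Workflow economics of arrayed versus separate embedding
#'
#' Compares processing all conditions on one array block against embedding
#' each condition as its own block: one block instead of `n_conditions`
#' blocks, hence an `n_conditions`-fold saving in sectioning, staining
#' reagents and slides. A 9-dose + control assay (10 conditions, 3 slides
#' per sample) needs 30 slides per protein when embedded separately.
#'
#' @param n_conditions number of experimental conditions.
#' @param replicates_per_condition spheroids per condition.
#' @param slides_per_sample slides stained per embedded sample.
#' @param layout an [array_layout()]; the array arm must have capacity for
#'   all spheroids.
#' @return an object of class `workflow_plan` with `blocks_separate`,
#'   `blocks_array`, `fold_saving`, `slides_separate`, `slides_array`.
#' @export
plan_workflow <- function(n_conditions, replicates_per_condition,
                          slides_per_sample = 3, layout = array_layout()) {
  stopifnot(inherits(layout, "array_layout"))
  n_spheroids <- n_conditions * replicates_per_condition
  if (n_spheroids > layout$capacity)
    stop(sprintf("capacity error: %d spheroids exceed the %d-well array",
                 n_spheroids, layout$capacity), call. = FALSE)
  structure(list(
    n_conditions = n_conditions,
    replicates_per_condition = replicates_per_condition,
    slides_per_sample = slides_per_sample,
    blocks_separate = n_conditions,
    blocks_array = 1L,
    fold_saving = n_conditions,
    slides_separate = n_conditions * slides_per_sample,
    slides_array = slides_per_sample,
    capacity = layout$capacity
  ), class = "workflow_plan")
}

#' @export
print.workflow_plan <- function(x, ...) {
  cat(sprintf(
    "Workflow: %d conditions x %d replicates; %d blocks vs 1 array (%d-fold saving); %d vs %d slides\n",
    x$n_conditions, x$replicates_per_condition, x$blocks_separate,
    x$fold_saving, x$slides_separate, x$slides_array))
  invisible(x)
}
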