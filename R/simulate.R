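# Ground-truthed synthetic generators. Every generator is a pure function
# of its spec + seed; the caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

disk_mask <- function(h, w, cy, cx, r) {
  dy <- (seq_len(h) - cy)
  dx <- (seq_len(w) - cx)
  outer(dy^2, dx^2, `+`) <= r^2
}

#' Specification of a synthetic stained section
#'
#' Describes an H-DAB-stained spheroid section for [render_section()].
#' In `"nuclear"` mode the section is a field of hematoxylin-absorbing
#' disk nuclei of which `n_positive` additionally absorb DAB; in
#' `"cytoplasmic"` mode it is a tissue disk with a concentric DAB-positive
#' region covering `positive_fraction` of the tissue area.
#'
#' @param width,height image size in pixels.
#' @param mode `"nuclear"` or `"cytoplasmic"`.
#' @param n_nuclei,n_positive nucleus counts (nuclear mode).
#' @param nucleus_radius nucleus radius in px.
#' @param min_distance minimum centre-to-centre distance between separate
#'   nuclei (default 2.5 radii, guaranteeing non-touching disks).
#' @param touching_pairs number of nucleus pairs placed at
#'   `pair_separation` radii apart (for watershed validation); pairs are
#'   counted within `n_nuclei` and are never DAB-positive unless
#'   `n_positive` exceeds the singles.
#' @param pair_separation pair centre distance in units of the radius.
#' @param positive_fraction target DAB-positive area fraction
#'   (cytoplasmic mode).
#' @param tissue_radius tissue disk radius in px (cytoplasmic mode);
#'   default 35% of the smaller image side.
#' @param h_density,dab_density stain optical-density amplitudes.
#' @param gain_amplitude peak relative amplitude of a smooth radial
#'   vignetting gain field (0 = flat illumination).
#' @param noise_sd additive Gaussian intensity noise (8-bit levels).
#' @param background_intensity incident white level.
#' @param pixel_size um/px calibration carried into the truth record.
#' @param nuclei optional explicit data frame (`cy`, `cx`, `r`,
#'   `positive`) overriding random placement.
#' @param seed RNG seed making the rendering deterministic.
#' @return an object of class `section_spec`.
#' @export
section_spec <- function(width = 256, height = 256,
                         mode = c("nuclear", "cytoplasmic"),
                         n_nuclei = 30, n_positive = 10,
                         nucleus_radius = 8,
                         min_distance = 2.5 * nucleus_radius,
                         touching_pairs = 0, pair_separation = 1.75,
                         positive_fraction = 0.25, tissue_radius = NULL,
                         h_density = 0.8, dab_density = 0.6,
                         gain_amplitude = 0, noise_sd = 2,
                         background_intensity = 255, pixel_size = 1,
                         nuclei = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (h_density < 0 || dab_density < 0)
    stop("stain densities must be nonnegative", call. = FALSE)
  if (mode == "cytoplasmic" &&
      (positive_fraction < 0 || positive_fraction > 1))
    stop("`positive_fraction` must be in [0, 1]", call. = FALSE)
  if (is.null(tissue_radius)) tissue_radius <- floor(0.35 * min(width, height))
  structure(as.list(environment()), class = "section_spec")
}

place_entities <- function(n, radii, offsets, h, w, min_distance,
                           max_tries = 20000L, max_restarts = 10L) {
  # entities keep min_distance between their nearest member disks, so the
  # required centre distance grows by both entities' member offsets
  for (attempt in seq_len(max_restarts)) {
    centres <- matrix(NA_real_, n, 2)
    placed <- 0L
    tries <- 0L
    while (placed < n && tries < max_tries) {
      tries <- tries + 1L
      m <- radii[placed + 1L] + 1
      cy <- runif(1, m + 1, h - m)
      cx <- runif(1, m + 1, w - m)
      need <- min_distance + offsets[placed + 1L] + offsets[seq_len(placed)]
      if (placed == 0L ||
          all((centres[seq_len(placed), 1] - cy)^2 +
              (centres[seq_len(placed), 2] - cx)^2 >= need^2)) {
        placed <- placed + 1L
        centres[placed, ] <- c(cy, cx)
      }
    }
    if (placed == n) return(centres)
  }
  stop("could not place all nuclei: image too small for the requested ",
       "count and spacing", call. = FALSE)
}

#' Render a synthetic stained section with ground truth
#'
#' Renders the section described by a [section_spec()] through the forward
#' Beer-Lambert model ([synthesize_rgb()]), applies the optional smooth
#' gain field, adds seeded Gaussian noise and clips to `[0, 255]`.
#'
#' @param spec a [section_spec()].
#' @param system the [stain_system()] used for synthesis.
#' @return list with `image` (RGB array) and `truth` (exact counts, areas
#'   and the generating parameters).
#' @export
render_section <- function(spec, system = stain_system()) {
  stopifnot(inherits(spec, "section_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    h_map <- matrix(0, h, w)
    d_map <- matrix(0, h, w)
    truth <- list(mode = spec$mode, seed = spec$seed,
                  pixel_size = spec$pixel_size)
    if (spec$mode == "nuclear") {
      nuc <- spec$nuclei
      if (is.null(nuc)) {
        r <- spec$nucleus_radius
        n_pairs <- spec$touching_pairs
        n_single <- spec$n_nuclei - 2L * n_pairs
        if (n_single < 0) stop("touching_pairs exceed n_nuclei", call. = FALSE)
        n_ent <- n_single + n_pairs
        ent_r <- c(rep(r, n_single),
                   rep(r * (1 + spec$pair_separation / 2), n_pairs))
        ent_off <- c(rep(0, n_single),
                     rep(r * spec$pair_separation / 2, n_pairs))
        centres <- place_entities(n_ent, ent_r, ent_off, h, w,
                                  spec$min_distance)
        nuc <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
        if (n_single > 0)
          nuc <- data.frame(cy = centres[seq_len(n_single), 1],
                            cx = centres[seq_len(n_single), 2], r = r)
        if (n_pairs > 0) {
          for (k in seq_len(n_pairs)) {
            ctr <- centres[n_single + k, ]
            ang <- runif(1, 0, pi)
            off <- spec$pair_separation * r / 2 * c(sin(ang), cos(ang))
            nuc <- rbind(nuc,
                         data.frame(cy = ctr[1] + off[1], cx = ctr[2] + off[2],
                                    r = r),
                         data.frame(cy = ctr[1] - off[1], cx = ctr[2] - off[2],
                                    r = r))
          }
        }
        pos <- rep(FALSE, nrow(nuc))
        if (spec$n_positive > 0)
          pos[sample.int(nrow(nuc), min(spec$n_positive, nrow(nuc)))] <- TRUE
        nuc$positive <- pos
      }
      for (i in seq_len(nrow(nuc))) {
        dm <- disk_mask(h, w, nuc$cy[i], nuc$cx[i], nuc$r[i])
        h_map[dm] <- spec$h_density
        if (nuc$positive[i]) d_map[dm] <- spec$dab_density
      }
      truth$nuclei <- nuc
      truth$n_nuclei <- nrow(nuc)
      truth$n_positive <- sum(nuc$positive)
      truth$percent_positive <-
        if (nrow(nuc)) 100 * sum(nuc$positive) / nrow(nuc) else NA_real_
    } else {
      R <- spec$tissue_radius
      tis <- disk_mask(h, w, (h + 1) / 2, (w + 1) / 2, R)
      h_map[tis] <- spec$h_density
      if (spec$positive_fraction > 0) {
        r_pos <- R * sqrt(spec$positive_fraction)
        posm <- disk_mask(h, w, (h + 1) / 2, (w + 1) / 2, r_pos) & tis
        d_map[posm] <- spec$dab_density
      } else posm <- matrix(FALSE, h, w)
      truth$tissue_px <- sum(tis)
      truth$dab_px <- sum(posm)
      truth$percent_positive <- 100 * sum(posm) / sum(tis)
      truth$nominal_fraction <- spec$positive_fraction
    }
    maps <- array(0, c(h, w, 3))
    maps[, , 1] <- h_map
    maps[, , 2] <- d_map
    img <- synthesize_rgb(maps, system, spec$background_intensity) * 1.0
    if (spec$gain_amplitude > 0) {
      cy <- (h + 1) / 2; cx <- (w + 1) / 2
      r2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
      gain <- 1 - spec$gain_amplitude * r2 / max(r2)
      for (c in 1:3) img[, , c] <- img[, , c] * gain
      truth$gain_field <- gain
    }
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
    list(image = img, truth = truth)
  })
}

#' Specification of synthetic bead-row cross-sections
#'
#' Describes the acrylic-bead embedding-depth experiment for
#' [render_bead_rows()]: per mold row, dark beads of radius
#' `radius_um` whose lower edges sit at a common plane plus per-bead
#' deviations. Defaults follow the reference experiment: 500-um-radius
#' beads imaged at 25 um/px, 6 rows per mold.
#'
#' @param n_rows number of mold rows (one image each).
#' @param beads_per_row beads in each row.
#' @param radius_um bead radius (um).
#' @param pixel_size um/px calibration.
#' @param plane_depth nominal lower-edge depth of the common plane (um).
#' @param deviations list of numeric vectors (um, one per row) of planted
#'   lower-edge deviations; when `NULL`, drawn from
#'   `N(0, deviation_sd)` and snapped to the pixel grid.
#' @param deviation_sd standard deviation (um) for random deviations.
#' @param seed RNG seed.
#' @return an object of class `bead_row_spec`.
#' @export
bead_row_spec <- function(n_rows = 6, beads_per_row = 11, radius_um = 500,
                          pixel_size = 25, plane_depth = 5000,
                          deviations = NULL, deviation_sd = 100, seed = 1) {
  if (!is.null(deviations)) {
    if (length(deviations) != n_rows)
      stop("`deviations` must have one vector per row", call. = FALSE)
    beads_per_row <- length(deviations[[1]])
  }
  structure(as.list(environment()), class = "bead_row_spec")
}

#' Render synthetic bead-row images with planted lower edges
#'
#' Rasterises each row as dark disks on a light background such that every
#' bead's bottom-most occupied row equals its planted lower edge exactly
#' (deviations are snapped to the pixel grid). The truth record lists the
#' per-bead lower edges, so [detect_beads()] and
#' [deviations_from_median_plane()] can be validated against planted
#' values.
#'
#' @param spec a [bead_row_spec()].
#' @return list with `images` (one grayscale matrix per row) and `truth`
#'   (data frame `row_id`, `bead`, `lower_edge_y`, `deviation`).
#' @export
render_bead_rows <- function(spec) {
  stopifnot(inherits(spec, "bead_row_spec"))
  with_seed(spec$seed, {
    ps <- spec$pixel_size
    r_px <- round(spec$radius_um / ps)
    spacing <- ceiling(2.6 * r_px)
    w <- spacing * spec$beads_per_row + spacing
    devs <- spec$deviations
    if (is.null(devs))
      devs <- replicate(spec$n_rows,
                        round(rnorm(spec$beads_per_row, 0,
                                    spec$deviation_sd) / ps) * ps,
                        simplify = FALSE)
    else
      devs <- lapply(devs, function(d) round(d / ps) * ps)
    images <- vector("list", spec$n_rows)
    truth <- NULL
    for (row in seq_len(spec$n_rows)) {
      d <- devs[[row]]
      lower_px <- round((spec$plane_depth + d) / ps)
      hgt <- max(lower_px) + 4 * r_px
      img <- matrix(220, hgt, w)
      for (b in seq_along(d)) {
        cy <- lower_px[b] - r_px
        cx <- spacing * b
        if (cy - r_px < 1) stop("bead extends above the image", call. = FALSE)
        bead <- disk_mask(hgt, w, cy, cx, r_px)
        # flattened contact facet where the bead rests on the common plane,
        # so the planted lower edge survives the median/opening filters
        flat_w <- max(3L, r_px %/% 4L)
        bead[(lower_px[b] - 3L):lower_px[b],
             (cx - flat_w):(cx + flat_w)] <- TRUE
        img[bead] <- 60
      }
      images[[row]] <- img
      truth <- rbind(truth, data.frame(
        row_id = row, bead = seq_along(d),
        lower_edge_y = lower_px * ps, deviation = d))
    }
    list(images = images, truth = truth)
  })
}

#' Simulate per-spheroid assay signals with outliers
#'
#' Draws sample and negative-control measurements from location-scale
#' normal distributions, replacing a fraction of draws with gross outliers
#' (shifted by `outlier_scale` spreads in a random direction) — the
#' situation the robust Z'-factor is designed for. Defaults emulate a
#' strongly expressed nuclear marker: 23 spheroids around 91% positive with
#' spread 11, low isotype controls.
#'
#' @param n_sample,n_control group sizes (>= 2).
#' @param median_sample,median_control group locations.
#' @param spread_sample,spread_control group scales (normal SD).
#' @param outlier_rate fraction of draws replaced by outliers, in `[0, 1]`.
#' @param outlier_scale outlier displacement in units of the group spread.
#' @param seed RNG seed.
#' @return an object of class `assay_signal`: list with numeric vectors
#'   `sample` and `control` and a `truth` record of the generating
#'   parameters.
#' @export
simulate_assay_signal <- function(n_sample = 23, n_control = 23,
                                  median_sample = 91, median_control = 5,
                                  spread_sample = 11, spread_control = 3,
                                  outlier_rate = 0.1, outlier_scale = 10,
                                  seed = 1) {
  if (n_sample < 2 || n_control < 2)
    stop("both groups need n >= 2", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("parameter error: `outlier_rate` must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    draw <- function(n, m, s) {
      x <- m + rnorm(n, 0, s)
      out <- runif(n) < outlier_rate
      x[out] <- m + outlier_scale * max(s, 1) * sample(c(-1, 1), sum(out),
                                                       replace = TRUE)
      x
    }
    structure(list(
      sample = draw(n_sample, median_sample, spread_sample),
      control = draw(n_control, median_control, spread_control),
      truth = list(median_sample = median_sample,
                   median_control = median_control,
                   spread_sample = spread_sample,
                   spread_control = spread_control,
                   outlier_rate = outlier_rate, seed = seed)
    ), class = "assay_signal")
  })
}

#' Simulate a 4PL dose-response table
#'
#' Generates responses from a four-parameter logistic curve plus seeded
#' Gaussian noise. The default design mirrors the reference etoposide
#' screen: 9 approximately half-log doses spanning 0.01-300 uM, a
#' proliferation readout falling from about 50% with IC50 0.9 uM and a
#' bottom plateau at zero.
#'
#' @param top,bottom,ic50,hill generating 4PL parameters.
#' @param doses dose grid (uM), default [half_log_doses()].
#' @param noise_sd Gaussian response noise SD.
#' @param n_replicates replicate responses per dose.
#' @param seed RNG seed.
#' @return data frame with columns `dose` and `response`; the generating
#'   parameters are attached as attribute `truth`.
#' @export
simulate_dose_response <- function(top = 50, bottom = 0, ic50 = 0.9,
                                   hill = 1, doses = half_log_doses(),
                                   noise_sd = 0, n_replicates = 1, seed = 1) {
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  with_seed(seed, {
    dose <- rep(doses, each = n_replicates)
    y <- predict_4pl(dose, top, bottom, ic50, hill)
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    out <- data.frame(dose = dose, response = y)
    attr(out, "truth") <- list(top = top, bottom = bottom, ic50 = ic50,
                               hill = hill, noise_sd = noise_sd, seed = seed)
    out
  })
}
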