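#' Default run configuration
#'
#' All tunable analysis parameters with their defaults. A YAML config file
#' (see [read_config()]) and per-call arguments override these. The
#' resolved configuration is echoed into every batch output directory for
#' provenance.
#'
#' @return a nested list of parameters.
#' @export
default_config <- function() {
  list(
    stain = list(h_vector = hdab_vectors$h, dab_vector = hdab_vectors$dab),
    background_intensity = 255,
    threshold = list(h_method = "isodata", dab_method = "fixed",
                     h_value = NULL, dab_value = 0.2),
    nuclear = list(min_area = 20, mode = "union"),
    pixel_size = 1,
    depth = list(pixel_size = 25, min_area = 10000, bin_width = 50),
    mad_scale = 1.4826,
    seed = 1
  )
}

#' Read a YAML run configuration
#'
#' Loads a YAML file and merges it over [default_config()] (file values
#' win; unspecified keys keep their defaults).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return resolved configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

image_extensions <- c("tif", "tiff", "png", "jpg", "jpeg")

#' Batch-quantify a folder of section images
#'
#' Runs the cytoplasmic or nuclear pipeline over every image in a folder
#' (sorted filename order), writing one CSV row per image, a QC overlay
#' image per input, and the resolved configuration. Per-file failures are
#' logged and skipped; the batch continues.
#'
#' @param input_dir folder containing only images (TIFF/PNG/JPEG).
#' @param pipeline `"cyto"` or `"nuclei"`.
#' @param config configuration list from [read_config()] /
#'   [default_config()].
#' @param out_dir output directory (created if needed).
#' @return data frame of results, invisibly, with attribute `n_failed`;
#'   the CSV is written to `out_dir/results.csv` and overlays under
#'   `out_dir/qc/`.
#' @export
run_batch <- function(input_dir, pipeline = c("cyto", "nuclei"),
                      config = default_config(), out_dir) {
  pipeline <- match.arg(pipeline)
  if (!dir.exists(input_dir)) stop("cannot read folder: ", input_dir,
                                   call. = FALSE)
  files <- sort(list.files(input_dir, full.names = TRUE,
                           pattern = paste0("\\.(",
                                            paste(image_extensions,
                                                  collapse = "|"),
                                            ")$"), ignore.case = TRUE))
  if (!length(files)) stop("no images found in ", input_dir, call. = FALSE)
  dir.create(file.path(out_dir, "qc"), recursive = TRUE, showWarnings = FALSE)
  system <- stain_system(config$stain$h_vector, config$stain$dab_vector)
  rows <- list()
  n_failed <- 0L
  for (f in files) {
    res <- tryCatch({
      img <- read_image(f)
      if (length(dim(img)) != 3L)
        stop("expected an RGB image")
      if (pipeline == "cyto") {
        r <- analyze_cytoplasmic(
          img, system,
          h_method = config$threshold$h_method,
          dab_method = config$threshold$dab_method,
          h_value = config$threshold$h_value,
          dab_value = config$threshold$dab_value,
          pixel_size = config$pixel_size,
          background_intensity = config$background_intensity)
        qc <- make_qc_overlay(img, attr(r, "tissue_mask"),
                              attr(r, "dab_mask"))
        row <- data.frame(
          image = basename(f),
          h_threshold = r$h_threshold, dab_threshold = r$dab_threshold,
          tissue_area_px = r$tissue_area_px, dab_area_px = r$dab_area_px,
          percent_positive = r$percent_positive)
      } else {
        r <- analyze_nuclear(
          img, system,
          h_method = config$threshold$h_method,
          dab_method = config$threshold$dab_method,
          h_value = config$threshold$h_value,
          dab_value = config$threshold$dab_value,
          min_area = config$nuclear$min_area,
          pixel_size = config$pixel_size,
          background_intensity = config$background_intensity,
          mode = config$nuclear$mode)
        qc <- make_qc_overlay(img, attr(r, "h_mask"), attr(r, "dab_mask"))
        row <- data.frame(
          image = basename(f),
          h_threshold = r$h_threshold, dab_threshold = r$dab_threshold,
          n_nuclei = r$n_nuclei_h, n_nuclei_dab = r$n_nuclei_dab,
          percent_positive = r$percent_positive)
      }
      write_image(qc, file.path(out_dir, "qc",
                                paste0(tools::file_path_sans_ext(basename(f)),
                                       "_qc.png")))
      row
    }, error = function(e) {
      message("FAILED ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[f]] <- res
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.csv(out, file.path(out_dir, "results.csv"), row.names = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config_used.yaml"))
  attr(out, "n_failed") <- n_failed
  invisible(out)
}

#' Batch embedding-depth analysis from a manifest
#'
#' Reads a manifest CSV (columns `path`, `row_id`, optionally `pixel_size`
#' and `angle`), detects beads in every row image and summarises the
#' deviations from each row's median plane. Images are rotated by the
#' manifest's `angle` (multiples of 90 degrees; levelling to the slide is
#' expected to happen at acquisition or via this flag).
#'
#' @param manifest path to the manifest CSV or a data frame.
#' @param min_area minimum bead area (um^2).
#' @param bin_width histogram bin width (um).
#' @param pixel_size default calibration when absent from the manifest.
#' @param out_dir optional output directory for `deviations.csv`,
#'   `summary.json` and `histogram.png`.
#' @return a `depth_summary`, invisibly when `out_dir` is given.
#' @export
run_depth <- function(manifest, min_area = 10000, bin_width = 50,
                      pixel_size = 25, out_dir = NULL) {
  man <- if (is.character(manifest)) read.csv(manifest) else manifest
  if (!all(c("path", "row_id") %in% names(man)))
    stop("manifest needs columns `path` and `row_id`", call. = FALSE)
  det <- NULL
  for (i in seq_len(nrow(man))) {
    img <- read_image(man$path[i])
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    ang <- if ("angle" %in% names(man)) man$angle[i] else 0
    if (ang %% 360 != 0) {
      k <- (ang %/% 90) %% 4
      for (j in seq_len(k)) img <- t(apply(img, 2, rev))
    }
    ps <- if ("pixel_size" %in% names(man)) man$pixel_size[i] else pixel_size
    det <- rbind(det, detect_beads(img, ps, min_area, man$row_id[i]))
  }
  summ <- deviations_from_median_plane(det, bin_width)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(deviation_um = summ$deviations),
              file.path(out_dir, "deviations.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n_beads = summ$n_beads, iqr = summ$iqr, p10_p90 = summ$p10_p90,
           bin_width = summ$histogram$bin_width,
           counts = summ$histogram$counts),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    grDevices::png(file.path(out_dir, "histogram.png"), 800, 500)
    plot(summ)
    grDevices::dev.off()
    return(invisible(summ))
  }
  summ
}
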