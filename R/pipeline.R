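# End-to-end pipeline: (optional) preprocess -> SCA decomposition -> circle
# transform detection -> quantification, with every artifact written next to
# a resolved-configuration stamp so a run can be reproduced exactly.
#
# Coordinate convention used everywhere (truth CSVs, detection CSVs,
# overlays): (row, col), 1-based, pixel centers at integer coordinates.

#' Run configuration for the full pipeline
#'
#' @param pixel_size Pixel pitch in um/pixel.
#' @param preprocess List: `enabled`, `crop` (`"square"` or `"circle"`),
#'   `core_spacing_px` (`NULL` skips the fiber-core low-pass). Phantom
#'   inputs default to no preprocessing.
#' @param sca An [sca_config()].
#' @param detect A [detect_config()].
#' @param size_cutoff_um Red/green diameter split in um.
#' @param seed Integer seed stamped into outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_size = 0.83,
                       preprocess = list(enabled = FALSE, crop = "square",
                                         core_spacing_px = NULL),
                       sca = sca_config(),
                       detect = detect_config(),
                       size_cutoff_um = 8,
                       seed = 1L) {
  structure(list(pixel_size = pixel_size, preprocess = preprocess,
                 sca = sca, detect = detect,
                 size_cutoff_um = size_cutoff_um, seed = as.integer(seed)),
            class = "run_config")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

config_to_json <- function(config) {
  jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}

#' Run the full SCA+CT pipeline on an image or phantom
#'
#' Executes preprocess (if enabled), [sca_decompose()], [detect_nuclei()]
#' and [compute_density()], and writes the artifact bundle into `out_dir`:
#' component TIFFs (`spatial`, `dct`, `curvelet`, `approx`), the objective
#' trace CSV, the detections CSV, the statistics JSON, a red/green overlay
#' PNG, and the resolved configuration (with package version stamp).
#'
#' @param input A file path (TIFF/PNG), a numeric image matrix, or a
#'   `phantom_image`.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @return List with `image`, `decomposition`, `detections`, `stats`,
#'   `overlay`, `out_dir`, invisibly.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL) {
  img <- if (is.character(input)) {
    read_image(input)
  } else if (inherits(input, "phantom_image")) {
    input$pixels
  } else if (is.matrix(input)) {
    clamp01(input)
  } else {
    stop("input must be a file path, matrix or phantom_image", call. = FALSE)
  }
  if (isTRUE(config$preprocess$enabled)) {
    img <- crop_fov(img, method = config$preprocess$crop)
    if (!is.null(config$preprocess$core_spacing_px)) {
      img <- remove_fiber_pattern(img, config$preprocess$core_spacing_px)
    }
    attr(img, "fov") <- NULL
  }
  dec <- sca_decompose(img, config$sca)
  det <- detect_nuclei(dec$components$nuclei, config$detect,
                       pixel_size = config$pixel_size)
  area <- image_area_mm2(dim(img), config$pixel_size)
  stats <- compute_density(det, area, config$size_cutoff_um)
  overlay <- render_overlay(img, det, config$size_cutoff_um)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_image(dec$components$nuclei, file.path(out_dir, "spatial.tif"))
    write_image(clamp01(dec$components$muscle),
                file.path(out_dir, "dct.tif"))
    write_image(clamp01(dec$components$adipose),
                file.path(out_dir, "curvelet.tif"))
    write_image(clamp01(dec$approximation),
                file.path(out_dir, "approx.tif"))
    utils::write.csv(
      data.frame(iteration = seq_along(dec$objective_trace) - 1L,
                 objective = dec$objective_trace),
      file.path(out_dir, "trace.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(det),
                     file.path(out_dir, "detections.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(n_nuclei = stats$n,
           total_density = stats$total_density,
           small_density = stats$small_density,
           large_density = stats$large_density,
           size_cutoff_um = stats$size_cutoff,
           analyzed_area_mm2 = stats$analyzed_area_mm2),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
    png::writePNG(overlay, file.path(out_dir, "overlay.png"))
    writeLines(c(
      as.character(config_to_json(config)),
      sprintf("// scact %s, R %s",
              as.character(utils::packageVersion("scact")),
              paste(R.version$major, R.version$minor, sep = "."))),
      file.path(out_dir, "run_config.json"))
  }
  invisible(list(image = img, decomposition = dec, detections = det,
                 stats = stats, overlay = overlay, out_dir = out_dir))
}

#' Compare two groups of per-image densities
#'
#' Cohort statistics used for margin assessment: Wilcoxon rank-sum p-value
#' on the per-image total densities and ROC/AUC with the Youden operating
#' point using density as the classifier score (group A is taken as the
#' positive class).
#'
#' @param densities_a,densities_b Numeric vectors of per-image densities.
#' @return List with `p_value`, `roc` (a `roc_result`), and group
#'   summaries.
#' @export
compare_density_groups <- function(densities_a, densities_b) {
  p <- wilcoxon_rank_sum(densities_a, densities_b)
  roc <- roc_auc(c(densities_a, densities_b),
                 c(rep(1L, length(densities_a)),
                   rep(0L, length(densities_b))))
  list(p_value = p, roc = roc,
       median_a = stats::median(densities_a),
       median_b = stats::median(densities_b))
}
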