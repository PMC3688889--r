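# Simulation-based error evaluation: match detections to phantom ground
# truth, compute percent error of recovered density, and sweep the error
# over nuclear size, density and tumor-to-muscle contrast ratio.

#' Match detections to ground-truth nuclei
#'
#' Greedy one-to-one matching: detections are visited in decreasing score
#' order and claim the nearest unclaimed true nucleus whose center lies
#' within that nucleus' true radius (a scale-appropriate tolerance across
#' the 4-18 px diameter range).
#'
#' @param detections A `detection_set`.
#' @param truth Ground-truth data frame with columns `row`, `col`,
#'   `radius_px` (as produced by the phantom generators).
#' @return List with `matches` (data frame of detection/truth index pairs
#'   and distances), `recall`, `precision`, and `precision_defined`
#'   (`FALSE` when there were no detections, in which case precision is
#'   reported as 1 by convention).
#' @export
match_detections <- function(detections, truth) {
  nd <- nrow(detections)
  nt <- nrow(truth)
  matches <- data.frame(detection = integer(), truth = integer(),
                        distance = numeric())
  if (nd > 0 && nt > 0) {
    ord <- order(-detections$score, detections$row, detections$col)
    claimed <- logical(nt)
    for (i in ord) {
      d2 <- (truth$row - detections$row[i])^2 +
        (truth$col - detections$col[i])^2
      ok <- !claimed & d2 <= truth$radius_px^2
      if (any(ok)) {
        j <- which(ok)[which.min(d2[ok])]
        claimed[j] <- TRUE
        matches <- rbind(matches,
                         data.frame(detection = i, truth = j,
                                    distance = sqrt(d2[j])))
      }
    }
  }
  nm <- nrow(matches)
  list(matches = matches,
       recall = if (nt > 0) nm / nt else 1,
       precision = if (nd > 0) nm / nd else 1,
       precision_defined = nd > 0)
}

#' Percent error between detected and true density
#'
#' `|detected - true| / true * 100`; overcounting and undercounting are
#' penalized symmetrically.
#'
#' @param detected_density,true_density Densities (any common unit);
#'   `true_density` must be positive.
#' @return Percent error.
#' @export
percent_error <- function(detected_density, true_density) {
  if (any(true_density <= 0)) {
    stop("true_density must be positive", call. = FALSE)
  }
  abs(detected_density - true_density) / true_density * 100
}

#' Sweep percent error over nuclear size, density and contrast ratio
#'
#' Full factorial simulation study: for every (diameter, density, ratio,
#' replicate) cell a phantom is generated (tumor-only when `ratio` is `NA`,
#' otherwise tumor+muscle at that contrast ratio), decomposed with SCA,
#' nuclei are detected in the spatial component, and detections are matched
#' to ground truth. Each replicate uses a distinct derived seed; the whole
#' table is reproducible bit-for-bit from `seed`.
#'
#' @param diameters Nucleus diameters in pixels.
#' @param densities Densities per 0.25 mm2.
#' @param ratios Contrast ratios (use `NA` for tumor-only phantoms).
#' @param replicates Phantom replicates per condition; >= 1.
#' @param base_spec A [phantom_spec()] providing shape, pixel size, blur and
#'   muscle texture.
#' @param sca_cfg An [sca_config()].
#' @param det_cfg A [detect_config()].
#' @param seed Integer master seed.
#' @param progress Print one line per condition as the sweep runs.
#' @return Data frame with one row per replicate: `diameter_px`,
#'   `density_per_qmm`, `ratio`, `replicate`, `seed`, `true_count`,
#'   `detected_count`, `percent_error`, `recall`, `precision`.
#' @export
sweep_error_surface <- function(diameters, densities, ratios = NA,
                                replicates = 1,
                                base_spec = phantom_spec(),
                                sca_cfg = sca_config(),
                                det_cfg = detect_config(),
                                seed = 1L, progress = FALSE) {
  stopifnot(length(diameters) >= 1, length(densities) >= 1,
            length(ratios) >= 1, replicates >= 1)
  seed <- as.integer(seed)
  grid <- expand.grid(diameter_px = diameters, density_per_qmm = densities,
                      ratio = ratios, replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  grid$seed <- seed + seq_len(nrow(grid)) - 1L
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- evaluate_condition(g$diameter_px, g$density_per_qmm, g$ratio,
                              g$seed, base_spec, sca_cfg, det_cfg)
    rows[[i]] <- cbind(g, res)
    if (progress) {
      message(sprintf(
        "d=%g px dens=%g ratio=%s rep=%d: err %.1f%% recall %.2f",
        g$diameter_px, g$density_per_qmm, format(g$ratio), g$replicate,
        res$percent_error, res$recall))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# One phantom -> decompose -> detect -> match cell of the sweep.
evaluate_condition <- function(diameter, density, ratio, seed,
                               base_spec, sca_cfg, det_cfg) {
  spec <- base_spec
  spec$nucleus_diameter <- diameter
  spec$density <- density
  spec$seed <- as.integer(seed)
  ph <- simulate_tumor(spec)
  if (!is.na(ratio)) {
    ph <- combine_tumor_muscle(ph, simulate_muscle(spec),
                               contrast_ratio = ratio)
  }
  dec <- suppressWarnings(sca_decompose(ph$pixels, sca_cfg))
  det <- detect_nuclei(dec$components$nuclei, det_cfg,
                       pixel_size = spec$pixel_size)
  mt <- match_detections(det, ph$truth)
  true_n <- nrow(ph$truth)
  data.frame(
    true_count = true_n, detected_count = nrow(det),
    percent_error = if (true_n > 0) percent_error(nrow(det), true_n) else NA,
    recall = mt$recall, precision = mt$precision)
}

#' Per-region detection metrics on a sweep-grid phantom
#'
#' Matches detections to ground truth over the whole image, then reports
#' recall, detection count and percent error of the recovered count within
#' each grid region (the way error is read off a single sweep image that
#' mixes sizes and densities).
#'
#' @param detections A `detection_set`.
#' @param truth Ground-truth data frame with a `region_id` column.
#' @param regions Region table from [sweep_grid()] (`$regions`).
#' @return `regions` augmented with `detected_count`, `recall`,
#'   `percent_error` columns.
#' @export
region_metrics <- function(detections, truth, regions) {
  mt <- match_detections(detections, truth)
  out <- regions
  out$detected_count <- NA_integer_
  out$recall <- NA_real_
  out$percent_error <- NA_real_
  for (k in seq_len(nrow(regions))) {
    rid <- regions$region_id[k]
    tix <- which(truth$region_id == rid)
    n_in <- sum(detections$row >= regions$row_min[k] &
                  detections$row <= regions$row_max[k] &
                  detections$col >= regions$col_min[k] &
                  detections$col <= regions$col_max[k])
    out$detected_count[k] <- n_in
    out$recall[k] <- if (length(tix) > 0) {
      sum(mt$matches$truth %in% tix) / length(tix)
    } else NA_real_
    out$percent_error[k] <- if (length(tix) > 0) {
      percent_error(n_in, length(tix))
    } else NA_real_
  }
  out
}

#' Contour plot of a percent-error sweep
#'
#' @param sweep Result of [sweep_error_surface()] (single contrast ratio).
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_error_surface <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  agg <- stats::aggregate(percent_error ~ diameter_px + density_per_qmm,
                          data = sweep, FUN = mean)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$diameter_px,
                                    y = .data$density_per_qmm,
                                    z = .data$percent_error)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(x = "nuclear diameter (px)",
                  y = expression("density (nuclei/0.25 mm"^2 * ")"),
                  fill = "% error")
}
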