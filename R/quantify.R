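# Quantitative readouts: nuclear diameter distributions, total and
# size-split densities per 0.25 mm2, red/green overlay rendering, and the
# cohort statistics (Wilcoxon rank-sum, ROC/AUC, Youden index).

#' Nuclear density and size statistics from a detection set
#'
#' Densities are expressed per 0.25 mm2 of analyzed area:
#' `density = count / analyzed_area * 0.25`. Nuclei are split at
#' `size_cutoff` um into small (`<= cutoff`) and large (`> cutoff`)
#' subsets, whose densities sum exactly to the total.
#'
#' @param detections A `detection_set` from [detect_nuclei()] (or any data
#'   frame with a `diameter_um` column).
#' @param analyzed_area Analyzed tissue area in mm2; > 0.
#' @param size_cutoff Diameter split point in um (default 8, the dip between
#'   the two modes of the nuclear diameter distribution).
#' @return An object of class `nuclei_stats`: list with `diameters` (um),
#'   `n`, `total_density`, `small_density`, `large_density`, `size_cutoff`,
#'   `analyzed_area_mm2`.
#' @export
compute_density <- function(detections, analyzed_area, size_cutoff = 8) {
  if (!is.numeric(analyzed_area) || length(analyzed_area) != 1 ||
      analyzed_area <= 0) {
    stop("analyzed_area must be a positive area in mm2", call. = FALSE)
  }
  d <- detections$diameter_um
  small <- sum(d <= size_cutoff)
  large <- sum(d > size_cutoff)
  structure(list(
    diameters = d, n = length(d),
    total_density = count_to_density(length(d), analyzed_area),
    small_density = count_to_density(small, analyzed_area),
    large_density = count_to_density(large, analyzed_area),
    size_cutoff = size_cutoff, analyzed_area_mm2 = analyzed_area
  ), class = "nuclei_stats")
}

#' @export
print.nuclei_stats <- function(x, ...) {
  cat(sprintf(
    "nuclei_stats: %d nuclei in %.4g mm2 | density %.1f /0.25 mm2 (<=%g um: %.1f, >%g um: %.1f)\n",
    x$n, x$analyzed_area_mm2, x$total_density, x$size_cutoff,
    x$small_density, x$size_cutoff, x$large_density))
  invisible(x)
}

#' Two-tailed Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 20 and no ties
#' are present; normal approximation with tie and continuity correction
#' otherwise. Two identical constant samples return `p = 1` with a warning.
#'
#' @param group_a,group_b Numeric vectors; both non-empty.
#' @return Two-tailed p-value.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1) {
    warning("all values identical across both groups; p = 1", call. = FALSE)
    return(1)
  }
  has_ties <- anyDuplicated(pooled) > 0
  exact <- !has_ties && length(pooled) <= 20
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  unname(res$p.value)
}

#' ROC curve, AUC and Youden operating point
#'
#' Computes the full ROC curve over all score thresholds, the area under it
#' by the trapezoidal rule (equal to the normalized Mann-Whitney U
#' statistic), and the Youden point maximizing
#' `sensitivity + specificity - 1`. Higher scores are taken to indicate the
#' positive class.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1, logical, or a two-level factor).
#' @return An object of class `roc_result`: list with `thresholds`,
#'   `sensitivities`, `specificities`, `auc`, `youden_threshold`,
#'   `youden_sensitivity`, `youden_specificity`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.factor(labels)) - 1L
  if (length(unique(labels)) != 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  j <- r$sensitivities + r$specificities - 1
  best <- which.max(j)
  structure(list(
    thresholds = r$thresholds,
    sensitivities = r$sensitivities,
    specificities = r$specificities,
    auc = as.numeric(r$auc),
    youden_threshold = r$thresholds[best],
    youden_sensitivity = r$sensitivities[best],
    youden_specificity = r$specificities[best]
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "roc_result: AUC %.3f | Youden point: sensitivity %.2f, specificity %.2f at threshold %.4g\n",
    x$auc, x$youden_sensitivity, x$youden_specificity, x$youden_threshold))
  invisible(x)
}

#' Render detections as a red/green overlay on the original image
#'
#' The original is contrast-stretched (constant images pass through
#' unchanged) and detections are drawn as filled circles: green for
#' diameters at or below `cutoff_um`, red above it.
#'
#' @param original Grayscale image matrix.
#' @param detections A `detection_set`.
#' @param cutoff_um Diameter split in um.
#' @return `rows x cols x 3` RGB array in `[0, 1]` (writable with
#'   [png::writePNG()]).
#' @export
render_overlay <- function(original, detections, cutoff_um = 8) {
  stop_if_not_image(original, "original")
  rng <- range(original)
  base <- if (rng[2] > rng[1]) (original - rng[1]) / (rng[2] - rng[1]) else
    original
  out <- array(rep(base, 3), c(dim(base), 3))
  for (i in seq_len(nrow(detections))) {
    r0 <- detections$row[i]; c0 <- detections$col[i]
    r <- detections$radius_px[i]
    rr <- max(1, floor(r0 - r)):min(nrow(base), ceiling(r0 + r))
    cc <- max(1, floor(c0 - r)):min(ncol(base), ceiling(c0 + r))
    inside <- outer((rr - r0)^2, (cc - c0)^2, `+`) <= r^2
    chan <- if (detections$diameter_um[i] > cutoff_um) 1L else 2L
    for (ch in 1:3) {
      patch <- out[rr, cc, ch]
      patch[inside] <- if (ch == chan) 1 else 0
      out[rr, cc, ch] <- patch
    }
  }
  out
}

#' Smoothed probability density of nuclear diameters
#'
#' Histogram in 1-um bins with a kernel-density overlay, as a plain list of
#' plotting data (no graphics device side effects).
#'
#' @param diameters Numeric diameters in um.
#' @return List with `breaks`, `counts`, `density_x`, `density_y`.
#' @export
diameter_distribution <- function(diameters) {
  if (length(diameters) == 0) {
    return(list(breaks = numeric(), counts = integer(),
                density_x = numeric(), density_y = numeric()))
  }
  breaks <- seq(floor(min(diameters)), ceiling(max(diameters)) + 1, by = 1)
  h <- graphics::hist(diameters, breaks = breaks, plot = FALSE)
  dn <- if (length(diameters) > 1 && stats::sd(diameters) > 0) {
    d <- stats::density(diameters)
    list(x = d$x, y = d$y)
  } else list(x = diameters[1], y = 1)
  list(breaks = h$breaks, counts = h$counts,
       density_x = dn$x, density_y = dn$y)
}
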