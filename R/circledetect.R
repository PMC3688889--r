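# Gradient-vote circular Hough transform ("circle transform") applied to the
# SCA nuclei component: edge pixels vote along +/- their gradient direction
# at each candidate radius; accumulator peaks give centers and radii of
# approximately circular, possibly overlapping nuclei.

#' Configuration of circle-transform nuclei detection
#'
#' @param radius_range Integer `[r_min, r_max]` candidate radii in pixels.
#'   The default `[2, 10]` covers nuclear diameters of 4-18 px (4-15 um at
#'   0.83 um/px).
#' @param accumulator_sigma Gaussian smoothing, in pixels, applied to each
#'   radius slice of the vote accumulator before peak picking.
#' @param score_threshold Detection threshold as a fraction of the
#'   accumulator maximum, in `(0, 1)`.
#' @param min_center_distance Minimum separation of accepted centers in
#'   pixels; `NULL` defaults to `r_min` (permits overlapping nuclei while
#'   suppressing duplicate peaks of one nucleus).
#' @param gradient_threshold Edge-pixel gate as a fraction of the maximum
#'   gradient magnitude.
#' @return An object of class `detect_config`.
#' @export
detect_config <- function(radius_range = c(2L, 10L),
                          accumulator_sigma = 1,
                          score_threshold = 0.5,
                          min_center_distance = NULL,
                          gradient_threshold = 0.1) {
  radius_range <- as.integer(round(radius_range))
  if (length(radius_range) != 2 || radius_range[1] <= 0 ||
      radius_range[1] >= radius_range[2]) {
    stop("radius_range must satisfy 0 < r_min < r_max", call. = FALSE)
  }
  if (score_threshold <= 0 || score_threshold >= 1) {
    stop("score_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(min_center_distance)) min_center_distance <- radius_range[1]
  structure(list(radius_range = radius_range,
                 accumulator_sigma = accumulator_sigma,
                 score_threshold = score_threshold,
                 min_center_distance = min_center_distance,
                 gradient_threshold = gradient_threshold),
            class = "detect_config")
}

image_gradient <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  gr[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  gc[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  list(gr = gr, gc = gc, mag = sqrt(gr^2 + gc^2))
}

#' Circle transform accumulator
#'
#' For every candidate radius, each edge pixel casts two votes (weighted by
#' its gradient magnitude) at the points one radius away along and against
#' its local gradient direction, covering both bright-on-dark and
#' dark-on-bright circles. Each radius slice is normalized by circumference,
#' smoothed, and the whole accumulator scaled to `[0, 1]`.
#'
#' @param img Image matrix.
#' @param radius_range Integer `[r_min, r_max]` in pixels.
#' @param config A [detect_config()] (supplies smoothing and edge gate).
#' @return 3-D array `rows x cols x radii` with attribute `"radii"`.
#' @export
circle_transform <- function(img, radius_range = c(2L, 10L),
                             config = detect_config(radius_range = radius_range)) {
  stop_if_not_image(img, "img")
  radii <- seq(radius_range[1], radius_range[2])
  h <- nrow(img); w <- ncol(img)
  acc <- array(0, c(h, w, length(radii)))
  attr(acc, "radii") <- radii
  g <- image_gradient(img)
  gmax <- max(g$mag)
  if (gmax == 0) return(acc)
  edge <- which(g$mag > config$gradient_threshold * gmax)
  if (length(edge) == 0) return(acc)
  er <- ((edge - 1) %% h) + 1
  ec <- ((edge - 1) %/% h) + 1
  ur <- g$gr[edge] / g$mag[edge]
  uc <- g$gc[edge] / g$mag[edge]
  wt <- g$mag[edge]
  for (k in seq_along(radii)) {
    r <- radii[k]
    slice <- numeric(h * w)
    for (s in c(-1, 1)) {
      vr <- round(er + s * r * ur)
      vc <- round(ec + s * r * uc)
      ok <- vr >= 1 & vr <= h & vc >= 1 & vc <= w
      if (any(ok)) {
        lin <- (vc[ok] - 1) * h + vr[ok]
        sums <- rowsum(wt[ok], lin)
        slice[as.integer(rownames(sums))] <-
          slice[as.integer(rownames(sums))] + sums[, 1]
      }
    }
    sl <- matrix(slice, h, w) / (2 * pi * r)
    if (config$accumulator_sigma > 0) {
      sl <- gaussian_blur(sl, config$accumulator_sigma)
    }
    acc[, , k] <- sl
  }
  amax <- max(acc)
  if (amax > 0) acc <- acc / amax
  attr(acc, "radii") <- radii
  acc
}

empty_detections <- function(pixel_size) {
  structure(data.frame(row = numeric(), col = numeric(),
                       radius_px = numeric(), diameter_um = numeric(),
                       score = numeric()),
            pixel_size = pixel_size, class = c("detection_set", "data.frame"))
}

#' Detect nuclei in the SCA spatial component
#'
#' Runs [circle_transform()], keeps accumulator cells that are local maxima
#' in their 3x3x3 neighborhood and exceed `score_threshold`, and accepts
#' peaks greedily by score (ties broken by row, then column, then radius)
#' subject to a minimum center distance. Deterministic.
#'
#' @param nuclei_component Image matrix (typically the nuclei component of
#'   [sca_decompose()], but any image works standalone).
#' @param config A [detect_config()].
#' @param pixel_size Pixel pitch in um/pixel (converts radii to diameters).
#' @return A `detection_set` data frame with columns `row`, `col`,
#'   `radius_px`, `diameter_um`, `score`.
#' @export
detect_nuclei <- function(nuclei_component, config = detect_config(),
                          pixel_size = 0.83) {
  stop_if_not_image(nuclei_component, "nuclei_component")
  if (config$radius_range[1] < 2) {
    warning("r_min below 2 px is under the resolvable scale", call. = FALSE)
  }
  acc <- circle_transform(nuclei_component, config$radius_range, config)
  radii <- attr(acc, "radii")
  if (max(acc) == 0) return(empty_detections(pixel_size))
  cand <- which(acc >= config$score_threshold)
  if (length(cand) == 0) return(empty_detections(pixel_size))
  h <- dim(acc)[1]; w <- dim(acc)[2]; nr <- dim(acc)[3]
  ci <- arrayInd(cand, dim(acc))
  # local 3x3x3 maximum test (ties count as maxima; lexicographic greedy
  # acceptance below keeps the result deterministic)
  is_max <- vapply(seq_len(nrow(ci)), function(i) {
    r0 <- ci[i, 1]; c0 <- ci[i, 2]; k0 <- ci[i, 3]
    nb <- acc[max(1, r0 - 1):min(h, r0 + 1),
              max(1, c0 - 1):min(w, c0 + 1),
              max(1, k0 - 1):min(nr, k0 + 1)]
    acc[r0, c0, k0] >= max(nb)
  }, logical(1))
  ci <- ci[is_max, , drop = FALSE]
  if (nrow(ci) == 0) return(empty_detections(pixel_size))
  sc <- acc[ci]
  ord <- order(-sc, ci[, 1], ci[, 2], ci[, 3])
  ci <- ci[ord, , drop = FALSE]
  sc <- sc[ord]
  # greedy non-maximum suppression: a candidate is dropped if its center
  # falls within max(min_center_distance, 0.8 * r) of an accepted detection
  # of radius r -- scale-aware so duplicate fragments of one nucleus are
  # suppressed while genuinely overlapping neighbors survive
  keep <- logical(nrow(ci))
  acc_r <- numeric(0); acc_c <- numeric(0); acc_sup <- numeric(0)
  for (i in seq_len(nrow(ci))) {
    sup_i <- max(config$min_center_distance, 0.8 * radii[ci[i, 3]])
    sup <- pmax(acc_sup, sup_i)
    if (length(acc_r) == 0 ||
        all((acc_r - ci[i, 1])^2 + (acc_c - ci[i, 2])^2 >= sup^2)) {
      keep[i] <- TRUE
      acc_r <- c(acc_r, ci[i, 1])
      acc_c <- c(acc_c, ci[i, 2])
      acc_sup <- c(acc_sup, sup_i)
    }
  }
  ci <- ci[keep, , drop = FALSE]
  sc <- sc[keep]
  rpx <- radii[ci[, 3]]
  structure(data.frame(row = ci[, 1], col = ci[, 2], radius_px = rpx,
                       diameter_um = 2 * rpx * pixel_size, score = sc),
            pixel_size = pixel_size,
            class = c("detection_set", "data.frame"))
}
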